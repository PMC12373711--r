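#' Two-sample t test
#'
#' Pooled-variance (Student's) t by default, Welch by flag. The sign
#' convention everywhere in the package is group1 minus group2, i.e.
#' positive t means higher values in the first (patient) group.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param variant "pooled" (default) or "welch".
#' @return list(t, df, p) with a two-tailed p.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      stop("degenerate input: both samples constant and equal")
    stop("degenerate input: both samples have zero variance")
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Cohen's D from summary statistics
#'
#' Signed standardized mean difference using the pooled SD:
#' d = (mean1 - mean2) / s_p with
#' s_p = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)).
#' Conventional magnitude anchors: 0.2 small, 0.5 medium, 0.8 large.
#'
#' @param mean1,sd1,n1 group-1 summary (patients by convention).
#' @param mean2,sd2,n2 group-2 summary.
#' @return Signed d (vectorized over its arguments).
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(sd1 <= 0) || any(sd2 <= 0)) stop("SDs must be positive")
  if (any(n1 < 2) || any(n2 < 2)) stop("need n >= 2 per group")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (any(sp2 <= 0)) stop("pooled variance is not positive")
  (mean1 - mean2) / sqrt(sp2)
}

#' Cohen's D from raw samples
#' @param x,y numeric samples.
#' @return Signed d.
#' @export
cohens_d_from_samples <- function(x, y) {
  cohens_d(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Chi-square test on a 2x2 table
#'
#' Pearson chi-square (df = 1) without continuity correction by default;
#' Yates correction and the exact (hypergeometric) test are available
#' because published tables do not always state which variant produced a
#' printed p.
#'
#' @param tab 2x2 matrix of counts with positive margins.
#' @param correction "none" (default), "yates" or "exact".
#' @return list(statistic, p); statistic is NA for the exact variant.
#' @export
chi_square_2x2 <- function(tab, correction = c("none", "yates", "exact")) {
  correction <- match.arg(correction)
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("2x2 table has a zero margin")
  if (correction == "exact") {
    ht <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p = unname(ht$p.value)))
  }
  ht <- suppressWarnings(
    stats::chisq.test(tab, correct = (correction == "yates")))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; order-preserving and q >= p elementwise
#' (so reapplying the adjustment never lowers a q-value; constant vectors
#' are fixed points).
#'
#' @param pvalues numeric vector in [0, 1] (NA allowed, propagated).
#' @return q-values, same length and order.
#' @export
fdr_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Region- and network-level group comparison
#'
#' The "point"-level analysis: for each of the seven networks, one row for
#' the whole network (network SUVmean compared as a single ROI) plus one
#' row per member region. Pooled t by default; FDR is applied within each
#' network's family of member regions (the whole-network rows form their
#' own family of seven).
#'
#' @param cohort a \code{cohort_table} containing both groups.
#' @param atlas an \code{atlas_definition} with voxel counts.
#' @param variant t-test variant, "pooled" or "welch".
#' @return data.frame with columns network, region (NA for whole-network
#'   rows), abbreviation, mean1, sd1, n1, mean2, sd2, n2, t, df, p, q,
#'   cohens_d. Group 1 is the first (patient) group label.
#' @export
region_comparison <- function(cohort, atlas, variant = "pooled") {
  stopifnot(inherits(cohort, "cohort_table"))
  g1 <- cohort$group_labels[1]
  g2 <- cohort$group_labels[2]
  suv1 <- group_suv(cohort, g1)
  suv2 <- group_suv(cohort, g2)
  if (nrow(suv1) < 2L || nrow(suv2) < 2L)
    stop("need both groups with at least 2 subjects")

  nt <- network_table(cohort, atlas)
  n1m <- group_network_suv(nt, g1)
  n2m <- group_network_suv(nt, g2)

  row_for <- function(net, region, abbrev, x, y) {
    ok <- !anyNA(x) && !anyNA(y)
    if (!ok) return(NULL)
    ht <- two_sample_t(x, y, variant)
    data.frame(network = net, region = region, abbreviation = abbrev,
               mean1 = mean(x), sd1 = stats::sd(x), n1 = length(x),
               mean2 = mean(y), sd2 = stats::sd(y), n2 = length(y),
               t = ht$t, df = ht$df, p = ht$p, q = NA_real_,
               cohens_d = cohens_d_from_samples(x, y),
               stringsAsFactors = FALSE)
  }

  rows <- list()
  for (net in YEO7_NETWORKS) {
    if (!anyNA(n1m[, net]) && !anyNA(n2m[, net]))
      rows[[length(rows) + 1L]] <-
        row_for(net, NA_character_, NA_character_, n1m[, net], n2m[, net])
    members <- atlas$regions[atlas$regions$network == net, , drop = FALSE]
    for (i in seq_len(nrow(members))) {
      a <- members$abbreviation[i]
      if (!(a %in% colnames(cohort$suv))) next
      x <- suv1[, a]; y <- suv2[, a]
      if (anyNA(x) || anyNA(y)) {
        warning("region ", a, " has missing values; excluded")
        next
      }
      rows[[length(rows) + 1L]] <- row_for(net, members$name[i], a, x, y)
    }
  }
  res <- do.call(rbind, rows)

  # FDR families: member regions within each network; whole-network rows
  # across the seven networks
  is_net_row <- is.na(res$region)
  res$q[is_net_row] <- fdr_bh(res$p[is_net_row])
  for (net in unique(res$network)) {
    sel <- res$network == net & !is_net_row
    if (any(sel)) res$q[sel] <- fdr_bh(res$p[sel])
  }
  rownames(res) <- NULL
  res
}

#' Voxel-wise two-sample comparison within a mask
#'
#' Pooled-variance t at every masked voxel, with BH-FDR over the masked
#' voxels (the mask — typically one network — is the multiple-testing
#' family). The significance mask at \code{alpha} is split by sign:
#' positive t = higher uptake in group 1 (patients).
#'
#' @param volumes named list of 3-D arrays, all on one grid.
#' @param groups factor/character of group labels per volume; the first
#'   level (or \code{group_labels[1]}) is group 1.
#' @param mask logical 3-D analysis mask, nonempty.
#' @param alpha FDR threshold (default 0.05).
#' @param group_labels optional explicit pair c(group1, group2).
#' @return Object of class \code{stat_map}: \code{t} (3-D array, NA
#'   outside mask), \code{q} (same), \code{mask}, \code{df},
#'   \code{sig_pos}, \code{sig_neg} (logical arrays at q < alpha).
#' @export
voxelwise_comparison <- function(volumes, groups, mask, alpha = 0.05,
                                 group_labels = NULL) {
  stopifnot(length(volumes) == length(groups))
  if (!any(mask)) stop("analysis mask is empty")
  if (is.null(group_labels)) {
    groups <- as.factor(groups)
    group_labels <- levels(groups)
  } else {
    groups <- factor(groups, levels = group_labels)
  }
  stopifnot(length(group_labels) == 2L)
  i1 <- which(groups == group_labels[1])
  i2 <- which(groups == group_labels[2])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need at least 2 subjects per group")

  vox <- which(mask)
  X <- vapply(volumes, function(v) {
    stopifnot(identical(dim(v), dim(mask)))
    v[vox]
  }, numeric(length(vox)))           # voxels x subjects
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)   # single-voxel mask

  m1 <- rowMeans(X[, i1, drop = FALSE]); m2 <- rowMeans(X[, i2, drop = FALSE])
  n1 <- length(i1); n2 <- length(i2)
  v1 <- rowSums((X[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((X[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  pval <- 2 * stats::pt(-abs(tval), df)
  qval <- fdr_bh(pval)

  shape <- dim(mask)
  tarr <- array(NA_real_, shape); tarr[vox] <- tval
  qarr <- array(NA_real_, shape); qarr[vox] <- qval
  sig <- array(FALSE, shape); sig[vox] <- qval < alpha
  structure(list(t = tarr, q = qarr, mask = mask, df = df, alpha = alpha,
                 sig_pos = sig & !is.na(tarr) & tarr > 0,
                 sig_neg = sig & !is.na(tarr) & tarr < 0),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("Stat map: ", sum(x$mask), " voxels, df = ", x$df, ", ",
      sum(x$sig_pos), " positive / ", sum(x$sig_neg),
      " negative suprathreshold voxels (q < ", x$alpha, ")\n", sep = "")
  invisible(x)
}

# 26-connectivity connected components of a logical 3-D array by
# queue-based flood fill; returns an integer label array (0 background).
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  offsets <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offsets <- offsets[rowSums(offsets != 0L) > 0L, , drop = FALSE]
  todo <- which(mask)
  current <- 0L
  for (start in todo) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue) > 0L) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k0 <- (v - 1L) %/% (d[1] * d[2])
      j0 <- ((v - 1L) %% (d[1] * d[2])) %/% d[1]
      i0 <- (v - 1L) %% d[1]
      ni <- i0 + offsets[, 1]; nj <- j0 + offsets[, 2]; nk <- k0 + offsets[, 3]
      ok <- ni >= 0L & ni < d[1] & nj >= 0L & nj < d[2] & nk >= 0L & nk < d[3]
      nb <- 1L + ni[ok] + d[1] * (nj[ok] + d[2] * nk[ok])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb) > 0L) {
        lab[nb] <- current
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Extract suprathreshold clusters from a stat map
#'
#' Connected components (26-connectivity) of the significance mask,
#' computed separately for positive-t and negative-t voxels. Cluster
#' centroids are the unweighted mean of member voxel centres mapped to
#' world (MNI mm) coordinates through the affine; peak t is the extreme
#' (signed) value. No minimum extent is imposed.
#'
#' @param statmap a \code{stat_map}, or a plain t array.
#' @param significance_mask logical 3-D array (defaults to the stat map's
#'   combined positive/negative significance masks).
#' @param affine 4x4 voxel-to-mm transform (R index i maps through
#'   \code{affine \%*\% c(i-1, ...)}).
#' @return data.frame(sign, cluster_size, x, y, z, peak_t), sorted by size
#'   descending within sign; empty for an empty mask.
#' @export
extract_clusters <- function(statmap, significance_mask = NULL, affine) {
  if (inherits(statmap, "stat_map")) {
    tarr <- statmap$t
    if (is.null(significance_mask))
      significance_mask <- statmap$sig_pos | statmap$sig_neg
  } else {
    tarr <- statmap
    if (is.null(significance_mask))
      stop("a significance mask is required with a plain t array")
  }
  stopifnot(identical(dim(tarr), dim(significance_mask)))
  empty <- data.frame(sign = character(0), cluster_size = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      peak_t = numeric(0), stringsAsFactors = FALSE)
  if (!any(significance_mask)) return(empty)

  one_sign <- function(maskk, sgn) {
    if (!any(maskk)) return(empty)
    lab <- label_components_26(maskk)
    out <- lapply(seq_len(max(lab)), function(cl) {
      vox <- which(lab == cl)
      idx0 <- arrayInd(vox, dim(lab)) - 1L       # 0-based voxel indices
      world <- idx0 %*% t(affine[1:3, 1:3]) +
        matrix(affine[1:3, 4], nrow(idx0), 3, byrow = TRUE)
      centroid <- colMeans(world)
      tv <- tarr[vox]
      data.frame(sign = sgn, cluster_size = length(vox),
                 x = centroid[1], y = centroid[2], z = centroid[3],
                 peak_t = tv[which.max(abs(tv))], stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    res[order(-res$cluster_size), , drop = FALSE]
  }

  pos <- significance_mask & !is.na(tarr) & tarr > 0
  neg <- significance_mask & !is.na(tarr) & tarr < 0
  res <- rbind(one_sign(pos, "positive"), one_sign(neg, "negative"))
  rownames(res) <- NULL
  res
}
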