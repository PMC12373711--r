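#' Pearson correlation with a two-tailed p
#'
#' r with p from the exact t transform t = r sqrt((n-2)/(1-r^2)) on n-2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length n >= 3 with positive
#'   variance.
#' @return list(r, n, p).
#' @export
corr_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), n = length(x), p = unname(ht$p.value))
}

#' Two-tailed p for a given Pearson r and sample size
#'
#' Closed form used to back-compute the p that corresponds to a reported
#' correlation at a known n (e.g. checking printed r/p pairs).
#'
#' @param r correlation in (-1, 1).
#' @param n sample size >= 3.
#' @return Two-tailed p.
#' @export
corr_p_from_r <- function(r, n) {
  stopifnot(all(abs(r) < 1), all(n >= 3))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), n - 2)
}

#' Correlations among the seven whole-network SUVmeans
#'
#' All 21 pairwise network-level correlations, by default on the pooled
#' cohort (both groups together — printed p-values of the reference
#' analyses back-compute to the pooled n), optionally per group.
#'
#' @param networks a \code{network_table}.
#' @param pooling "pooled" (default) or "per_group".
#' @return data.frame(group, network_i, network_j, r, n, p); 21 rows per
#'   stratum.
#' @export
internetwork_corr <- function(networks, pooling = c("pooled", "per_group")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(networks, "network_table"))
  strata <- if (pooling == "pooled") list(pooled = networks$network_suv)
  else {
    stats::setNames(
      lapply(networks$group_labels,
             function(g) group_network_suv(networks, g)),
      networks$group_labels)
  }
  out <- list()
  for (s in names(strata)) {
    m <- strata[[s]]
    nets <- colnames(m)
    for (i in seq_len(ncol(m) - 1L)) {
      for (j in (i + 1L):ncol(m)) {
        cr <- corr_with_p(m[, i], m[, j])
        out[[length(out) + 1L]] <- data.frame(
          group = s, network_i = nets[i], network_j = nets[j],
          r = cr$r, n = cr$n, p = cr$p, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation of each network's SUVmean with its member regions
#'
#' For every network, correlates the whole-network SUVmean with each
#' member region's SUVmean across subjects (pooled cohort). The member
#' region is by default NOT removed from the network mean — the raw
#' part-whole correlation is what reference analyses report — but a
#' leave-one-out mode recomputes the network mean without the region under
#' test (voxel-count weights preserved).
#'
#' @param cohort a \code{cohort_table}.
#' @param networks a \code{network_table} computed from the same subjects.
#' @param atlas an \code{atlas_definition} (voxel counts needed for
#'   leave-one-out).
#' @param leave_one_out logical (default FALSE).
#' @param fdr apply BH-FDR per network family (default FALSE; raw p is
#'   the default report).
#' @return data.frame(network, region, abbreviation, r, n, p[, q],
#'   significant).
#' @export
intranetwork_region_corr <- function(cohort, networks, atlas,
                                     leave_one_out = FALSE, fdr = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(networks, "network_table"))
  if (!identical(cohort$subjects$subject, networks$subjects$subject))
    stop("cohort and network table must cover the same subjects")
  out <- list()
  for (net in YEO7_NETWORKS) {
    members <- atlas$regions[atlas$regions$network == net, , drop = FALSE]
    members <- members[members$abbreviation %in% colnames(cohort$suv), ,
                       drop = FALSE]
    if (nrow(members) == 0L) next
    netvals <- networks$network_suv[, net]
    if (anyNA(netvals)) next
    w <- atlas$voxel_counts[as.character(members$id)]
    for (i in seq_len(nrow(members))) {
      a <- members$abbreviation[i]
      ref <- netvals
      if (leave_one_out) {
        if (nrow(members) < 2L) next   # the region IS the network
        others <- setdiff(seq_len(nrow(members)), i)
        wo <- w[others]
        ref <- as.vector(cohort$suv[, members$abbreviation[others],
                                    drop = FALSE] %*% wo / sum(wo))
      }
      cr <- corr_with_p(ref, cohort$suv[, a])
      out[[length(out) + 1L]] <- data.frame(
        network = net, region = members$name[i], abbreviation = a,
        r = cr$r, n = cr$n, p = cr$p, stringsAsFactors = FALSE)
    }
  }
  skipped <- setdiff(colnames(cohort$suv),
                     atlas$regions$abbreviation[
                       atlas$regions$network != "unassigned"])
  if (length(skipped) > 0L)
    warning("region(s) not in any network skipped: ",
            paste(skipped, collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  if (fdr) {
    res$q <- NA_real_
    for (net in unique(res$network)) {
      sel <- res$network == net
      res$q[sel] <- fdr_bh(res$p[sel])
    }
  }
  res$significant <- res$p < 0.05
  rownames(res) <- NULL
  res
}
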