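#' Convert Gaussian FWHM to sigma
#'
#' sigma = FWHM / (2 * sqrt(2 * ln 2)) = FWHM / 2.3548.
#'
#' @param fwhm full width at half maximum, mm (nonnegative).
#' @return sigma in mm.
#' @export
fwhm_to_sigma <- function(fwhm) {
  if (any(fwhm < 0)) stop("fwhm must be nonnegative")
  fwhm / (2 * sqrt(2 * log(2)))
}

# Separable zero-padded Gaussian convolution of a 3-D array. sigma is
# given in mm and converted per axis with the voxel size; kernels are
# truncated at 4 sigma and normalized to unit sum, so a constant interior
# stays constant and a delta maps to a discrete Gaussian profile.
smooth_gaussian <- function(vol, fwhm_mm, voxel_mm) {
  stopifnot(length(dim(vol)) == 3L)
  if (fwhm_mm == 0) return(vol)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  sigma_mm <- fwhm_to_sigma(fwhm_mm)
  for (axis in 1:3) {
    sig_vox <- sigma_mm / voxel_mm[axis]
    if (sig_vox <= 0) next
    half <- max(1L, ceiling(4 * sig_vox))
    kern <- stats::dnorm(seq(-half, half), sd = sig_vox)
    kern <- kern / sum(kern)
    vol <- convolve_axis(vol, kern, axis)
  }
  vol
}

# 1-D convolution along one array axis via a banded matrix product,
# zero padding outside the grid.
convolve_axis <- function(vol, kern, axis) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = d[axis])
  n <- d[axis]
  half <- (length(kern) - 1L) / 2L
  B <- matrix(0, n, n)
  for (off in -half:half) {
    idx <- seq_len(n)
    keep <- idx + off >= 1L & idx + off <= n
    B[cbind(idx[keep], idx[keep] + off)] <- kern[off + half + 1L]
  }
  out <- B %*% m
  aperm(array(out, dim = d[perm]), order(perm))
}

#' Globally normalize an SUV volume
#'
#' Divides the volume by its mean over a whole-brain binary mask, the
#' standard correction for between-subject variability in injected dose.
#' The masked mean of the result is exactly 1, and the operation is
#' invariant to any positive rescaling of the input (hence idempotent).
#'
#' @param volume 3-D nonnegative SUV grid.
#' @param brain_mask logical 3-D grid, same shape; must be nonempty with a
#'   positive masked mean.
#' @return The normalized volume.
#' @export
global_normalize <- function(volume, brain_mask) {
  stopifnot(identical(dim(volume), dim(brain_mask)))
  if (!any(brain_mask)) stop("brain mask is empty")
  g <- mean(volume[brain_mask])
  if (g <= 0) stop("global mean over the mask is not positive")
  volume / g
}

#' Whole-brain mask of all atlas-labeled voxels
#'
#' The default brain mask for synthetic data: every voxel carrying any
#' region label.
#'
#' @param atlas an \code{atlas_definition} with a label volume.
#' @return Logical 3-D array.
#' @export
brain_mask_from_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "atlas_definition"))
  if (is.null(atlas$label_volume)) stop("atlas has no label volume")
  array(atlas$label_volume != 0L, dim = dim(atlas$label_volume))
}

#' Region-wise SUVmean of a volume
#'
#' Unweighted mean of the (normalized) volume over each region's voxels.
#'
#' @param volume 3-D grid on the atlas grid.
#' @param atlas an \code{atlas_definition} with a label volume.
#' @return Named numeric vector (names = region abbreviations, in
#'   catalogue order); regions with zero voxels get NA with a warning.
#' @export
roi_suvmean <- function(volume, atlas) {
  stopifnot(inherits(atlas, "atlas_definition"))
  if (is.null(atlas$label_volume)) stop("atlas has no label volume")
  if (!identical(dim(volume), dim(atlas$label_volume)))
    stop("volume shape ", paste(dim(volume), collapse = "x"),
         " does not match atlas grid ",
         paste(dim(atlas$label_volume), collapse = "x"))
  lab <- atlas$label_volume
  nz <- lab != 0L
  sums <- rowsum(volume[nz], group = lab[nz])
  ids_present <- as.integer(rownames(sums))
  counts <- atlas$voxel_counts[as.character(ids_present)]
  means <- stats::setNames(rep(NA_real_, nrow(atlas$regions)),
                           atlas$regions$abbreviation)
  means[match(ids_present, atlas$regions$id)] <- sums[, 1] / counts
  if (anyNA(means))
    warning("region(s) with no voxels return NA SUVmean: ",
            paste(names(means)[is.na(means)], collapse = ", "))
  means
}

#' Network-level SUVmean
#'
#' The mean over all voxels of each network's mask. Accepts either a
#' volume (direct voxel average over the mask) or a per-region SUVmean
#' vector (voxel-count-weighted mean of member regions); the two routes
#' agree exactly. An unweighted mean of region means is available for
#' sensitivity checks.
#'
#' @param source 3-D volume or named per-region vector (names = region
#'   abbreviations).
#' @param atlas an \code{atlas_definition}; voxel counts are required.
#' @param weighted logical; if FALSE, region vectors are averaged without
#'   voxel-count weights (volume input ignores this flag).
#' @return Named 7-vector in canonical network order; networks with zero
#'   voxels get NA with a warning.
#' @export
network_suvmean <- function(source, atlas, weighted = TRUE) {
  stopifnot(inherits(atlas, "atlas_definition"))
  out <- stats::setNames(rep(NA_real_, 7L), YEO7_NETWORKS)
  if (is.array(source) && length(dim(source)) == 3L) {
    if (is.null(atlas$label_volume)) stop("atlas has no label volume")
    for (net in YEO7_NETWORKS) {
      m <- network_mask(atlas, net)
      if (any(m)) out[net] <- mean(source[m])
    }
  } else {
    v <- source
    stopifnot(!is.null(names(v)))
    if (weighted && is.null(atlas$voxel_counts))
      stop("voxel counts required to aggregate a region vector")
    for (net in YEO7_NETWORKS) {
      members <- atlas$regions$abbreviation[atlas$regions$network == net]
      members <- intersect(members, names(v))
      if (length(members) == 0L) next
      if (weighted) {
        ids <- atlas$regions$id[match(members, atlas$regions$abbreviation)]
        w <- atlas$voxel_counts[as.character(ids)]
        if (sum(w) > 0) out[net] <- sum(v[members] * w) / sum(w)
      } else {
        out[net] <- mean(v[members])
      }
    }
  }
  if (anyNA(out))
    warning("network(s) with no voxels return NA: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Subjects x networks SUVmean table
#'
#' Aggregates a cohort's region-level SUVmean matrix to the seven
#' canonical networks (voxel-count-weighted by default), carrying the
#' group labels along — the substrate of all network-level ("plane")
#' analyses.
#'
#' @param cohort a \code{cohort_table}.
#' @param atlas an \code{atlas_definition} with voxel counts.
#' @param weighted passed to \code{\link{network_suvmean}}.
#' @return Object of class \code{network_table}: \code{subjects}
#'   (data.frame), \code{network_suv} (subjects x 7 matrix, canonical
#'   column order).
#' @export
network_table <- function(cohort, atlas, weighted = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  mat <- t(apply(cohort$suv, 1L, network_suvmean, atlas = atlas,
                 weighted = weighted))
  colnames(mat) <- YEO7_NETWORKS
  structure(list(subjects = cohort$subjects, network_suv = mat,
                 group_labels = cohort$group_labels),
            class = "network_table")
}

#' @export
print.network_table <- function(x, ...) {
  cat("Network table:", nrow(x$network_suv), "subjects x 7 networks\n")
  invisible(x)
}

#' Network-level SUV submatrix of one group
#' @param networks a \code{network_table}.
#' @param group a group label.
#' @return subjects x 7 matrix.
#' @export
group_network_suv <- function(networks, group) {
  stopifnot(inherits(networks, "network_table"))
  networks$network_suv[networks$subjects$group == group, , drop = FALSE]
}
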