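#' Default covariate specification
#'
#' Covariate mix of a two-group clinical FDG-PET cohort: age, BMI and
#' fasting blood sugar as per-group normal draws, sex and four vascular
#' risk factors as per-group Bernoulli prevalences. The default values
#' reproduce the demographic structure of a 174-patient / 206-control
#' cerebrovascular cohort (e.g. hypertension prevalence 52/174 vs 39/206).
#'
#' @return data.frame with one row per covariate: \code{name},
#'   \code{type} ("continuous" or "binary"), and per-group parameters
#'   (\code{mean1,sd1,mean2,sd2} or \code{prev1,prev2}).
#' @export
default_covariate_specs <- function() {
  data.frame(
    name  = c("age", "male", "bmi", "fbs",
              "smoking", "hypertension", "diabetes", "hyperlipidemia"),
    type  = c("continuous", "binary", "continuous", "continuous",
              "binary", "binary", "binary", "binary"),
    mean1 = c(53.75, NA, 24.22, 5.78, NA, NA, NA, NA),
    sd1   = c(7.78, NA, 3.19, 1.60, NA, NA, NA, NA),
    mean2 = c(53.00, NA, 24.02, 5.55, NA, NA, NA, NA),
    sd2   = c(18.42, NA, 3.08, 1.20, NA, NA, NA, NA),
    prev1 = c(NA, 101 / 174, NA, NA, 28 / 174, 52 / 174, 30 / 174, 44 / 174),
    prev2 = c(NA, 132 / 206, NA, NA, 35 / 206, 39 / 206, 26 / 206, 58 / 206),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic cohort design
#'
#' A design fixes everything the simulator needs: group sizes, per-region
#' baseline SUVmean and SD, the within-network inter-subject correlation,
#' optional additive mean shifts in designated regions of one group
#' ("point" effects), optional overrides of single inter-subject
#' correlations ("edge" effects), covariate specifications, and a seed.
#'
#' Baselines default to one deterministic draw (from \code{seed}) in the
#' range typical of globally normalized grey-matter SUVmean, 0.78-1.35 with
#' SDs 0.04-0.10.
#'
#' @param atlas an \code{atlas_definition}; its catalogue names the regions.
#' @param n_per_group integer 2-vector, group sizes (patients, controls).
#' @param baseline_means,baseline_sds named numeric vectors (names =
#'   region abbreviations) or NULL for the deterministic default draw.
#' @param network_correlation within-network inter-subject correlation rho,
#'   a single value in (-1, 1) or a named vector per network.
#' @param point_effects data.frame(region, group, delta): additive SUV mean
#'   shift for one region in one group; NULL for none.
#' @param edge_effects data.frame(region_i, region_j, group, rho): target
#'   inter-subject correlation for one region pair in one group (both
#'   regions must share a network); NULL for none.
#' @param covariate_specs as \code{\link{default_covariate_specs}}; NULL
#'   drops covariates.
#' @param group_labels character 2-vector, default c("CSVD", "HC").
#' @param seed integer master seed.
#' @return Object of class \code{cohort_design}.
#' @export
cohort_design <- function(atlas,
                          n_per_group = c(174L, 206L),
                          baseline_means = NULL,
                          baseline_sds = NULL,
                          network_correlation = 0.3,
                          point_effects = NULL,
                          edge_effects = NULL,
                          covariate_specs = default_covariate_specs(),
                          group_labels = c("CSVD", "HC"),
                          seed = 1L) {
  stopifnot(inherits(atlas, "atlas_definition"),
            length(n_per_group) == 2L, all(n_per_group >= 2L),
            length(group_labels) == 2L)
  regions <- atlas$regions
  abbr <- regions$abbreviation

  if (is.null(baseline_means) || is.null(baseline_sds)) {
    rng <- local({
      set.seed(seed + 1000L)
      list(means = stats::runif(nrow(regions), 0.78, 1.35),
           sds = stats::runif(nrow(regions), 0.04, 0.10))
    })
    if (is.null(baseline_means)) baseline_means <- stats::setNames(rng$means, abbr)
    if (is.null(baseline_sds)) baseline_sds <- stats::setNames(rng$sds, abbr)
  }
  stopifnot(all(abbr %in% names(baseline_means)),
            all(abbr %in% names(baseline_sds)))
  baseline_means <- baseline_means[abbr]
  baseline_sds <- baseline_sds[abbr]
  if (any(baseline_sds <= 0)) stop("all baseline SDs must be positive")

  nets <- setdiff(unique(regions$network), "unassigned")
  if (length(network_correlation) == 1L && is.null(names(network_correlation)))
    network_correlation <- stats::setNames(rep(network_correlation,
                                               length(nets)), nets)
  stopifnot(all(nets %in% names(network_correlation)))
  if (any(abs(network_correlation) >= 1))
    stop("network correlations must lie in (-1, 1)")

  check_effect_frame <- function(df, cols) {
    if (is.null(df)) return(NULL)
    stopifnot(is.data.frame(df), all(cols %in% names(df)))
    df
  }
  point_effects <- check_effect_frame(point_effects,
                                      c("region", "group", "delta"))
  edge_effects <- check_effect_frame(edge_effects,
                                     c("region_i", "region_j", "group", "rho"))
  if (!is.null(edge_effects) && any(abs(edge_effects$rho) >= 1))
    stop("edge-effect correlations must lie in (-1, 1)")

  structure(list(atlas = atlas, n_per_group = as.integer(n_per_group),
                 baseline_means = baseline_means, baseline_sds = baseline_sds,
                 network_correlation = network_correlation,
                 point_effects = point_effects, edge_effects = edge_effects,
                 covariate_specs = covariate_specs,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "cohort_design")
}

# Per-group correlation matrix for the regions of one network:
# equicorrelation rho off the diagonal, with any edge effects overriding
# single entries. Equivalent to the shared-latent-factor construction
# x = mu + sigma * (sqrt(rho) z_net + sqrt(1-rho) eps) when no edge is
# overridden.
build_block_correlation <- function(abbrs, rho, edge_effects, group_label) {
  k <- length(abbrs)
  R <- matrix(rho, k, k)
  diag(R) <- 1
  dimnames(R) <- list(abbrs, abbrs)
  if (!is.null(edge_effects)) {
    ee <- edge_effects[edge_effects$group == group_label &
                         edge_effects$region_i %in% abbrs &
                         edge_effects$region_j %in% abbrs, , drop = FALSE]
    if (nrow(ee) > 0L) {
      for (r in seq_len(nrow(ee))) {
        R[ee$region_i[r], ee$region_j[r]] <- ee$rho[r]
        R[ee$region_j[r], ee$region_i[r]] <- ee$rho[r]
      }
    }
  }
  R
}

ensure_positive_definite <- function(R, label) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-10) return(R)
  warning("correlation block for ", label,
          " is not positive definite; applying nearest-PD repair")
  rep <- Matrix::nearPD(R, corr = TRUE)
  R2 <- as.matrix(rep$mat)
  ev2 <- eigen(R2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) <= 0)
    stop("correlation block for ", label,
         " is not positive definite even after repair")
  dimnames(R2) <- dimnames(R)
  R2
}

#' Simulate a cohort from a design
#'
#' Per group, subject region-vectors are drawn from a multivariate normal
#' whose covariance is block-structured: one equicorrelated block per
#' network (off-block zero), with single entries overridden by any edge
#' effects; means are baselines plus any applicable point effects.
#' Covariates are drawn independently of the SUV values. Draws below 0.01
#' SUV are resampled (SUV is positive; at realistic parameters this is a
#' vanishing-probability event). Fully reproducible for a fixed seed.
#'
#' @param design a \code{\link{cohort_design}}.
#' @return Object of class \code{cohort_table}: \code{subjects} (data.frame
#'   with subject id, group, covariates) and \code{suv} (subjects x regions
#'   matrix, columns named by region abbreviation).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  regions <- design$atlas$regions
  abbr <- regions$abbreviation
  set.seed(design$seed)

  n <- design$n_per_group
  groups <- design$group_labels
  suv <- matrix(NA_real_, nrow = sum(n), ncol = length(abbr),
                dimnames = list(NULL, abbr))
  row_group <- rep(groups, times = n)

  for (g in 1:2) {
    rows <- which(row_group == groups[g])
    mu <- design$baseline_means
    if (!is.null(design$point_effects)) {
      pe <- design$point_effects[design$point_effects$group == groups[g], ,
                                 drop = FALSE]
      if (nrow(pe) > 0L) {
        bad <- setdiff(pe$region, abbr)
        if (length(bad) > 0L)
          stop("point effect names unknown region(s): ",
               paste(bad, collapse = ", "))
        mu[pe$region] <- mu[pe$region] + pe$delta
      }
    }
    # network blocks
    for (net in setdiff(unique(regions$network), "unassigned")) {
      members <- abbr[regions$network == net]
      R <- build_block_correlation(members,
                                   design$network_correlation[[net]],
                                   design$edge_effects, groups[g])
      R <- ensure_positive_definite(R, paste(groups[g], net))
      S <- diag(design$baseline_sds[members], length(members)) %*% R %*%
        diag(design$baseline_sds[members], length(members))
      draws <- MASS::mvrnorm(length(rows), mu = mu[members], Sigma = S)
      draws <- matrix(draws, nrow = length(rows))
      suv[rows, members] <- draws
    }
    # unassigned regions: independent
    una <- abbr[regions$network == "unassigned"]
    if (length(una) > 0L) {
      for (a in una)
        suv[rows, a] <- stats::rnorm(length(rows), mu[a],
                                     design$baseline_sds[a])
    }
  }

  # truncation: resample the (practically impossible) non-positive draws
  low <- which(suv < 0.01)
  tries <- 0L
  while (length(low) > 0L && tries < 100L) {
    cols <- ((low - 1L) %/% nrow(suv)) + 1L
    suv[low] <- stats::rnorm(length(low),
                             design$baseline_means[cols],
                             design$baseline_sds[cols])
    low <- which(suv < 0.01)
    tries <- tries + 1L
  }

  subjects <- data.frame(
    subject = sprintf("S%03d", seq_len(sum(n))),
    group = factor(row_group, levels = groups),
    stringsAsFactors = FALSE
  )
  if (!is.null(design$covariate_specs)) {
    cs <- design$covariate_specs
    for (i in seq_len(nrow(cs))) {
      vals <- numeric(sum(n))
      for (g in 1:2) {
        rows <- which(row_group == groups[g])
        if (cs$type[i] == "continuous") {
          vals[rows] <- stats::rnorm(length(rows),
                                     cs[[paste0("mean", g)]][i],
                                     cs[[paste0("sd", g)]][i])
        } else {
          vals[rows] <- stats::rbinom(length(rows), 1L,
                                      cs[[paste0("prev", g)]][i])
        }
      }
      subjects[[cs$name[i]]] <- vals
    }
  }

  structure(list(subjects = subjects, suv = suv,
                 group_labels = groups, design_seed = design$seed),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("Cohort:", paste(paste0(names(tab), "=", tab), collapse = ", "),
      "|", ncol(x$suv), "regions\n")
  invisible(x)
}

#' SUV submatrix of one group
#' @param cohort a \code{cohort_table}.
#' @param group a group label.
#' @return subjects x regions matrix for that group.
#' @export
group_suv <- function(cohort, group) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!(group %in% levels(cohort$subjects$group)))
    stop("unknown group: ", group)
  cohort$suv[cohort$subjects$group == group, , drop = FALSE]
}

#' Write / read a cohort table as TSV
#'
#' Layout: one row per subject, columns \code{subject, group,
#' <covariates...>, <region abbreviations...>}.
#'
#' @param cohort a \code{cohort_table}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cbind(cohort$subjects, as.data.frame(cohort$suv))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param group_labels the two group labels, first = patients.
#' @export
read_cohort <- function(path, group_labels = c("CSVD", "HC")) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "group") %in% names(df)))
  cov_guess <- intersect(default_covariate_specs()$name, names(df))
  suv_cols <- setdiff(names(df), c("subject", "group", cov_guess))
  suv <- as.matrix(df[, suv_cols, drop = FALSE])
  subjects <- df[, c("subject", "group", cov_guess), drop = FALSE]
  subjects$group <- factor(subjects$group, levels = group_labels)
  structure(list(subjects = subjects, suv = suv,
                 group_labels = group_labels, design_seed = NA_integer_),
            class = "cohort_table")
}

#' Render per-subject PET volumes from a cohort
#'
#' Paints each subject's region SUVmean into the region's voxels of the
#' atlas label volume, adds independent Gaussian voxel noise, then smooths
#' with the requested FWHM. Background voxels are 0.
#'
#' @param cohort a \code{cohort_table}.
#' @param atlas an \code{atlas_definition} with label volume; every cohort
#'   region must exist in the atlas.
#' @param voxel_noise_sd SD of additive voxel noise, SUV units.
#' @param fwhm_mm isotropic Gaussian smoothing FWHM in mm (0 = none).
#' @param subjects optional subset of subject ids.
#' @return Named list of 3-D arrays, one per subject.
#' @export
render_volumes <- function(cohort, atlas, voxel_noise_sd = 0, fwhm_mm = 0,
                           subjects = NULL) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(atlas, "atlas_definition"))
  if (is.null(atlas$label_volume)) stop("atlas has no label volume")
  if (fwhm_mm < 0) stop("fwhm must be nonnegative")
  missing_regions <- setdiff(colnames(cohort$suv), atlas$regions$abbreviation)
  if (length(missing_regions) > 0L)
    stop("cohort region(s) missing from atlas: ",
         paste(missing_regions, collapse = ", "))

  ids <- atlas$regions$id[match(colnames(cohort$suv),
                                atlas$regions$abbreviation)]
  lab <- atlas$label_volume
  # lookup: label value -> column of suv
  lut <- rep(NA_integer_, max(atlas$regions$id))
  lut[ids] <- seq_along(ids)
  nz <- which(lab != 0L)
  cols <- lut[lab[nz]]
  if (anyNA(cols))
    stop("atlas labels present in volume with no cohort region")
  vox_mm <- sqrt(colSums(atlas$affine[1:3, 1:3]^2))

  sel <- if (is.null(subjects)) cohort$subjects$subject else subjects
  out <- vector("list", length(sel))
  names(out) <- sel
  for (s in sel) {
    row <- match(s, cohort$subjects$subject)
    if (is.na(row)) stop("unknown subject: ", s)
    vol <- array(0, dim = dim(lab))
    vol[nz] <- cohort$suv[row, cols]
    if (voxel_noise_sd > 0)
      vol[nz] <- vol[nz] + stats::rnorm(length(nz), 0, voxel_noise_sd)
    if (fwhm_mm > 0)
      vol <- smooth_gaussian(vol, fwhm_mm, vox_mm)
    out[[s]] <- vol
  }
  out
}

#' Write rendered volumes to NIfTI files
#' @param volumes named list of 3-D arrays (as from
#'   \code{\link{render_volumes}}).
#' @param atlas the atlas whose affine the volumes share.
#' @param dir output directory; files are named \code{<subject>.nii.gz}.
#' @return Invisibly, the vector of paths.
#' @export
write_volumes <- function(volumes, atlas, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- sqrt(colSums(atlas$affine[1:3, 1:3]^2))
  paths <- character(length(volumes))
  for (i in seq_along(volumes)) {
    img <- RNifti::asNifti(volumes[[i]])
    RNifti::pixdim(img) <- vox
    RNifti::sform(img) <- structure(atlas$affine, code = 2L)
    RNifti::qform(img) <- structure(atlas$affine, code = 2L)
    paths[i] <- file.path(dir, paste0(names(volumes)[i], ".nii.gz"))
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}
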