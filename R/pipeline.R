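#' Format a p-value the way clinical tables print it
#'
#' Three decimals with a "<0.001" floor.
#' @param p numeric vector.
#' @return character vector.
#' @export
fmt_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Format "count (percent)" for a categorical covariate
#' @param count positive cases.
#' @param n group size.
#' @return e.g. "101 (58.05)" — percentages to two decimals.
#' @export
fmt_count_pct <- function(count, n) {
  sprintf("%d (%.2f)", as.integer(count), 100 * count / n)
}

#' Format "mean (SD)"
#' @param m,s mean and SD.
#' @param digits decimals (default 2).
#' @return e.g. "53.75 (7.78)".
#' @export
fmt_mean_sd <- function(m, s, digits = 2) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"), m, s)
}

#' Demographic comparison table
#'
#' One row per covariate: continuous covariates as mean (SD) per group
#' with a pooled two-sample t p; binary covariates as count (%) per group
#' with a Pearson chi-square p. A covariate with a single observed level
#' is reported without a test (warning).
#'
#' @param cohort a \code{cohort_table} with covariates.
#' @param chi_correction chi-square variant for categorical rows.
#' @return data.frame(characteristic, group1, group2, p, test) plus
#'   numeric column p_value.
#' @export
demographic_table <- function(cohort, chi_correction = "none") {
  stopifnot(inherits(cohort, "cohort_table"))
  covs <- setdiff(names(cohort$subjects), c("subject", "group"))
  if (length(covs) == 0L) stop("cohort has no covariates")
  g1 <- cohort$group_labels[1]; g2 <- cohort$group_labels[2]
  in1 <- cohort$subjects$group == g1
  in2 <- cohort$subjects$group == g2
  n1 <- sum(in1); n2 <- sum(in2)

  rows <- lapply(covs, function(cv) {
    v <- cohort$subjects[[cv]]
    binary <- all(v %in% c(0, 1))
    if (binary) {
      c1 <- sum(v[in1]); c2 <- sum(v[in2])
      tab <- rbind(c(c1, n1 - c1), c(c2, n2 - c2))
      if (any(colSums(tab) == 0)) {
        warning("covariate ", cv, " has a single level; no test emitted")
        p <- NA_real_; test <- "none"
      } else {
        p <- chi_square_2x2(tab, chi_correction)$p
        test <- "chi-square"
      }
      data.frame(characteristic = cv,
                 group1 = fmt_count_pct(c1, n1),
                 group2 = fmt_count_pct(c2, n2),
                 p = fmt_p(p), test = test, p_value = p,
                 stringsAsFactors = FALSE)
    } else {
      if (stats::var(v[in1]) == 0 && stats::var(v[in2]) == 0 &&
          isTRUE(all.equal(mean(v[in1]), mean(v[in2])))) {
        warning("covariate ", cv, " is constant; no test emitted")
        p <- NA_real_; test <- "none"
      } else {
        p <- two_sample_t(v[in1], v[in2], "pooled")$p
        test <- "two-sample t"
      }
      data.frame(characteristic = cv,
                 group1 = fmt_mean_sd(mean(v[in1]), stats::sd(v[in1])),
                 group2 = fmt_mean_sd(mean(v[in2]), stats::sd(v[in2])),
                 p = fmt_p(p), test = test, p_value = p,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  attr(res, "n_per_group") <- stats::setNames(c(n1, n2), c(g1, g2))
  res
}

#' Validate a pipeline configuration
#'
#' @param mode "simulate", "region_table" or "volumes".
#' @param out_dir output directory for the report bundle.
#' @param seed master seed.
#' @param permutations B for edge permutation tests (>= 1).
#' @param alpha FDR threshold in (0, 1).
#' @param t_variant "pooled" or "welch".
#' @param fwhm_mm smoothing FWHM applied when rendering synthetic volumes.
#' @param atlas an \code{atlas_definition}, or NULL to use the packaged
#'   fixture atlas (simulate mode).
#' @param design a \code{cohort_design} for simulate mode (NULL = default
#'   design on the atlas).
#' @param cohort_path TSV path for region_table mode.
#' @param volume_paths,group_table for volumes mode: named NIfTI paths and
#'   a data.frame(subject, group).
#' @param render_volumes logical; in simulate mode also render volumes and
#'   run the voxel-wise stage.
#' @param voxel_noise_sd voxel noise when rendering.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("simulate", "region_table", "volumes"),
                            out_dir, seed = 1L, permutations = 10000L,
                            alpha = 0.05, t_variant = "pooled",
                            fwhm_mm = 10, atlas = NULL, design = NULL,
                            cohort_path = NULL, volume_paths = NULL,
                            group_table = NULL, render_volumes = FALSE,
                            voxel_noise_sd = 0.05) {
  mode <- match.arg(mode)
  if (permutations < 1L) stop("permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (fwhm_mm < 0) stop("fwhm must be nonnegative")
  t_variant <- match.arg(t_variant, c("pooled", "welch"))
  if (mode == "region_table" && is.null(cohort_path))
    stop("region_table mode requires cohort_path")
  if (mode == "volumes" && (is.null(volume_paths) || is.null(group_table)))
    stop("volumes mode requires volume_paths and group_table")
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 permutations = as.integer(permutations), alpha = alpha,
                 t_variant = t_variant, fwhm_mm = fwhm_mm, atlas = atlas,
                 design = design, cohort_path = cohort_path,
                 volume_paths = volume_paths, group_table = group_table,
                 render_volumes = render_volumes,
                 voxel_noise_sd = voxel_noise_sd),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys of \code{\link{pipeline_config}} (mode, out_dir, seed,
#' permutations, alpha, t_variant, fwhm_mm, cohort_path, render_volumes,
#' voxel_noise_sd) plus optional atlas paths \code{atlas_volume} /
#' \code{atlas_regions}.
#'
#' @param path YAML file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  atlas <- NULL
  if (!is.null(y$atlas_volume))
    atlas <- load_atlas(y$atlas_volume, y$atlas_regions)
  args <- y[intersect(names(y),
                      c("mode", "out_dir", "seed", "permutations", "alpha",
                        "t_variant", "fwhm_mm", "cohort_path",
                        "render_volumes", "voxel_noise_sd"))]
  do.call(pipeline_config, c(args, list(atlas = atlas)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full point-line-plane pipeline
#'
#' Executes, in order: cohort acquisition (simulate / read table / extract
#' from volumes), demographic comparison, region- and network-level group
#' comparison ("point"), optional voxel-wise comparison with cluster
#' extraction, intra- and inter-network edge permutation tests ("line"),
#' and network-level correlation analyses ("plane"). All tables are
#' written as TSV under \code{config$out_dir} together with a YAML run
#' manifest recording the seed, permutation count, package version, stage
#' counts and output file hashes.
#'
#' @param config a \code{pipeline_config}.
#' @return Invisibly, a list with every intermediate result and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_counts <- list()

  # --- acquire atlas + cohort -------------------------------------------
  atlas <- config$atlas
  cohort <- NULL
  volumes <- NULL
  if (config$mode == "simulate") {
    if (is.null(atlas))
      atlas <- stage("atlas", make_fixture_atlas(seed = config$seed))
    design <- config$design
    if (is.null(design))
      design <- stage("design", cohort_design(atlas, seed = config$seed))
    cohort <- stage("simulate", simulate_cohort(design))
    if (config$render_volumes)
      volumes <- stage("render", render_volumes(
        cohort, atlas, voxel_noise_sd = config$voxel_noise_sd,
        fwhm_mm = config$fwhm_mm))
  } else if (config$mode == "region_table") {
    if (is.null(atlas)) stop("region_table mode requires an atlas")
    cohort <- stage("read_cohort", read_cohort(config$cohort_path))
  } else {
    if (is.null(atlas)) stop("volumes mode requires an atlas")
    mask <- brain_mask_from_atlas(atlas)
    volumes <- stage("read_volumes", lapply(config$volume_paths, function(p) {
      v <- RNifti::readNifti(p)
      global_normalize(array(as.vector(v), dim = dim(v)), mask)
    }))
    suv <- stage("extract", t(vapply(volumes, roi_suvmean, atlas = atlas,
                                     numeric(nrow(atlas$regions)))))
    gt <- config$group_table
    cohort <- structure(list(
      subjects = data.frame(subject = gt$subject,
                            group = factor(gt$group),
                            stringsAsFactors = FALSE),
      suv = suv, group_labels = levels(factor(gt$group)),
      design_seed = NA_integer_), class = "cohort_table")
  }

  out <- list(atlas = atlas, cohort = cohort)
  files <- character(0)

  # --- demographics ------------------------------------------------------
  if (ncol(cohort$subjects) > 2L) {
    out$demographics <- stage("demographics", demographic_table(cohort))
    files <- c(files, write_tsv(out$demographics,
                                file.path(config$out_dir, "demographics.tsv")))
  }

  # --- point: region/network comparison ---------------------------------
  out$region_comparison <- stage(
    "region_comparison", region_comparison(cohort, atlas, config$t_variant))
  log_counts$regions_tested <- sum(!is.na(out$region_comparison$region))
  files <- c(files, write_tsv(
    format_region_comparison(out$region_comparison),
    file.path(config$out_dir, "region_comparison.tsv")))

  # --- point: voxelwise + clusters (volume modes) ------------------------
  if (!is.null(volumes)) {
    groups <- cohort$subjects$group[match(names(volumes),
                                          cohort$subjects$subject)]
    clusters <- list()
    vox_in_masks <- 0L
    for (net in YEO7_NETWORKS) {
      m <- network_mask(atlas, net)
      if (!any(m)) next
      vox_in_masks <- vox_in_masks + sum(m)
      sm <- stage(paste0("voxelwise_", net), voxelwise_comparison(
        volumes, groups, m, alpha = config$alpha,
        group_labels = cohort$group_labels))
      cl <- extract_clusters(sm, affine = atlas$affine)
      if (nrow(cl) > 0L) cl <- cbind(network = net, cl)
      clusters[[net]] <- cl
    }
    log_counts$voxels_in_masks <- vox_in_masks
    out$clusters <- do.call(rbind, clusters[vapply(clusters, nrow, 1L) > 0])
    cl_out <- if (is.null(out$clusters))
      data.frame(network = character(0), sign = character(0),
                 cluster_size = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), peak_t = numeric(0))
    else out$clusters
    files <- c(files, write_tsv(cl_out,
                                file.path(config$out_dir, "clusters.tsv")))
  }

  # --- line: intra-network and inter-network edges ----------------------
  out$intranetwork_edges <- stage("intranetwork_edges", intranetwork_edges(
    cohort, atlas, B = config$permutations, seed = config$seed))
  log_counts$edges_tested <- sum(vapply(out$intranetwork_edges, nrow, 1L))
  for (net in names(out$intranetwork_edges))
    files <- c(files, write_tsv(
      format_edges(out$intranetwork_edges[[net]]),
      file.path(config$out_dir, paste0("edges_", net, ".tsv"))))

  networks <- stage("network_table", network_table(cohort, atlas))
  out$networks <- networks
  out$internetwork_edges <- stage("internetwork_edges",
                                  internetwork_connectivity(
                                    networks, B = config$permutations,
                                    seed = config$seed))
  files <- c(files, write_tsv(format_edges(out$internetwork_edges),
                              file.path(config$out_dir,
                                        "internetwork_edges.tsv")))

  # --- plane: network correlations --------------------------------------
  out$internetwork_corr <- stage("internetwork_corr",
                                 internetwork_corr(networks))
  files <- c(files, write_tsv(out$internetwork_corr,
                              file.path(config$out_dir,
                                        "internetwork_corr.tsv")))
  out$region_network_corr <- stage("region_network_corr",
                                   intranetwork_region_corr(
                                     cohort, networks, atlas))
  files <- c(files, write_tsv(out$region_network_corr,
                              file.path(config$out_dir,
                                        "region_network_corr.tsv")))

  # --- manifest ----------------------------------------------------------
  manifest <- list(
    seed = config$seed, permutations = config$permutations,
    alpha = config$alpha, t_variant = config$t_variant,
    mode = config$mode,
    package_version = as.character(utils::packageVersion("metaconn")),
    counts = log_counts,
    output_hashes = as.list(stats::setNames(
      unname(tools::md5sum(sort(files))), basename(sort(files)))))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  out$manifest <- manifest
  invisible(out)
}

# Region-comparison table in the layout of a published ROI table:
# M(SD) per group, p, q, Cohen's D (SUV to 3 decimals).
format_region_comparison <- function(rc) {
  data.frame(
    network = rc$network,
    region = ifelse(is.na(rc$region), "(whole network)", rc$region),
    abbreviation = ifelse(is.na(rc$abbreviation), "-", rc$abbreviation),
    group1_m_sd = fmt_mean_sd(rc$mean1, rc$sd1, 3),
    group2_m_sd = fmt_mean_sd(rc$mean2, rc$sd2, 3),
    p = fmt_p(rc$p), q = fmt_p(rc$q),
    cohens_d = sprintf("%.2f", rc$cohens_d),
    stringsAsFactors = FALSE)
}

format_edges <- function(es) {
  data.frame(node_i = es$node_i, node_j = es$node_j,
             r1 = sprintf("%.3f", es$r1), r2 = sprintf("%.3f", es$r2),
             delta = sprintf("%.3f", es$delta),
             p = fmt_p(es$p), q = fmt_p(es$q), stringsAsFactors = FALSE)
}
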