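#' Reference ROI summary statistics from a published two-group cohort
#'
#' Per-network and per-region SUVmean summaries (mean, SD per group,
#' printed p and effect size) of a 174-patient / 206-control FDG-PET
#' cohort, shipped for worked examples and effect-size regression checks:
#' Cohen's D recomputed from the printed means/SDs at n = 174/206
#' reproduces the printed magnitude column.
#'
#' @return data.frame with columns network, scope ("network" or
#'   "region"), region, mean1, sd1, mean2, sd2, p_printed, d_printed,
#'   plus n1 = 174, n2 = 206.
#' @export
reference_roi_stats <- function() {
  df <- utils::read.delim(
    system.file("extdata", "roi_reference_stats.tsv", package = "metaconn"),
    sep = "\t", stringsAsFactors = FALSE)
  df$n1 <- 174L
  df$n2 <- 206L
  df
}

#' Reference demographic counts and summaries of the same cohort
#'
#' Group sizes 174 / 206; binary covariates as positive counts,
#' continuous ones as mean/SD, with the printed test p.
#'
#' @return data.frame with columns characteristic, type, count1, mean1,
#'   sd1, count2, mean2, sd2, p_printed, plus n1/n2.
#' @export
reference_demographics <- function() {
  df <- utils::read.delim(
    system.file("extdata", "demographics_reference.tsv",
                package = "metaconn"),
    sep = "\t", stringsAsFactors = FALSE)
  df$n1 <- 174L
  df$n2 <- 206L
  df
}

#' Reference network-vs-region correlation pairs of the same cohort
#'
#' The printed (r, p) pairs of the network-versus-member-region
#' correlation analysis on the pooled cohort (n = 380). Rows whose
#' printed p was below the "<0.001" floor carry NA in p_printed.
#'
#' @return data.frame(network, region, r_printed, p_printed, n = 380).
#' @export
reference_network_region_corr <- function() {
  df <- utils::read.delim(
    system.file("extdata", "network_region_corr_reference.tsv",
                package = "metaconn"),
    sep = "\t", stringsAsFactors = FALSE)
  df$n <- 380L
  df
}
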