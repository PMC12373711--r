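# shared fixtures, built in code at load time

# 14-region atlas (2 regions per network) on a 24^3 grid, 3 mm voxels
fixture_atlas <- function(seed = 7L) make_fixture_atlas(c(24L, 24L, 24L), 2L, seed = seed)

# deterministic baselines in the plausible SUV range, one per abbreviation
flat_baselines <- function(atlas, mean = 1, sd = 0.08) {
  list(means = stats::setNames(rep(mean, nrow(atlas$regions)),
                               atlas$regions$abbreviation),
       sds = stats::setNames(rep(sd, nrow(atlas$regions)),
                             atlas$regions$abbreviation))
}

# null design: no effects, optionally zero within-network correlation
null_design <- function(atlas, rho = 0, n = c(174L, 206L), seed = 1L,
                        covariates = NULL) {
  b <- flat_baselines(atlas)
  cohort_design(atlas, n_per_group = n, baseline_means = b$means,
                baseline_sds = b$sds, network_correlation = rho,
                covariate_specs = covariates, seed = seed)
}

# hand-built cohort_table from an suv matrix and group sizes
manual_cohort <- function(suv, n1, n2, group_labels = c("CSVD", "HC")) {
  structure(list(
    subjects = data.frame(
      subject = sprintf("S%03d", seq_len(n1 + n2)),
      group = factor(rep(group_labels, times = c(n1, n2)),
                     levels = group_labels),
      stringsAsFactors = FALSE),
    suv = suv, group_labels = group_labels, design_seed = NA_integer_),
    class = "cohort_table")
}
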