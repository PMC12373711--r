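test_that("null design reproduces its baselines within sampling error in both groups", {
  atlas <- fixture_atlas()
  design <- null_design(atlas, rho = 0, seed = 5)
  cohort <- simulate_cohort(design)
  expect_true(all(cohort$suv > 0))
  for (g in c("CSVD", "HC")) {
    m <- group_suv(cohort, g)
    tol <- 4 * design$baseline_sds / sqrt(nrow(m))
    expect_true(all(abs(colMeans(m) - design$baseline_means) < tol))
  }
})

test_that("the same seed reproduces the cohort exactly; a different seed does not", {
  atlas <- fixture_atlas()
  d <- cohort_design(atlas, seed = 42)
  c1 <- simulate_cohort(d)
  c2 <- simulate_cohort(d)
  expect_identical(c1$suv, c2$suv)
  expect_identical(c1$subjects, c2$subjects)
  c3 <- simulate_cohort(cohort_design(atlas, seed = 43))
  expect_false(identical(c1$suv, c3$suv))
})

test_that("a Table-2-scale point effect is detectable with high power", {
  # +0.048 SUV on one region in the patient group, SD 0.08, n = 174/206:
  # a medium effect (d = 0.6) that a two-sample t should reject at
  # alpha = 0.05 nearly always
  atlas <- fixture_atlas()
  b <- flat_baselines(atlas, mean = 0.814, sd = 0.08)
  rejections <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    d <- cohort_design(atlas, baseline_means = b$means, baseline_sds = b$sds,
                       network_correlation = 0,
                       point_effects = data.frame(region = "SMN_2",
                                                  group = "CSVD",
                                                  delta = 0.048),
                       covariate_specs = NULL, seed = 1000L + r)
    cohort <- simulate_cohort(d)
    ht <- two_sample_t(group_suv(cohort, "CSVD")[, "SMN_2"],
                       group_suv(cohort, "HC")[, "SMN_2"])
    rejections <- rejections + (ht$p < 0.05)
  }
  expect_gte(rejections / n_rep, 0.95)
})

test_that("edge effects bend only the targeted correlation, leaving means and other edges alone", {
  atlas <- fixture_atlas()
  ee <- data.frame(region_i = "DAN_1", region_j = "DAN_2",
                   group = "CSVD", rho = 0.8)
  d <- null_design(atlas, rho = 0.3, n = c(4000L, 4000L), seed = 9)
  d$edge_effects <- ee
  cohort <- simulate_cohort(d)
  r1 <- stats::cor(group_suv(cohort, "CSVD"))
  r2 <- stats::cor(group_suv(cohort, "HC"))
  expect_equal(r1["DAN_1", "DAN_2"], 0.8, tolerance = 0.03)
  expect_equal(r2["DAN_1", "DAN_2"], 0.3, tolerance = 0.06)
  # untouched within-network edges stay at rho = 0.3 in both groups
  expect_equal(r1["VIS_1", "VIS_2"], 0.3, tolerance = 0.06)
  # cross-network edges stay near zero, means stay at baseline
  expect_lt(abs(r1["DAN_1", "VIS_1"]), 0.05)
  expect_true(all(abs(colMeans(cohort$suv) - d$baseline_means) < 0.01))
})

test_that("covariates are drawn per group with the designed prevalences", {
  atlas <- fixture_atlas()
  d <- cohort_design(atlas, n_per_group = c(2000L, 2000L), seed = 21)
  cohort <- simulate_cohort(d)
  hyp <- cohort$subjects$hypertension
  in1 <- cohort$subjects$group == "CSVD"
  expect_equal(mean(hyp[in1]), 52 / 174, tolerance = 0.05)
  expect_equal(mean(hyp[!in1]), 39 / 206, tolerance = 0.05)
  expect_equal(mean(cohort$subjects$age[in1]), 53.75, tolerance = 1)
})

test_that("noise-free unsmoothed rendering reproduces the region table exactly", {
  atlas <- fixture_atlas()
  cohort <- simulate_cohort(null_design(atlas, seed = 2, n = c(3L, 3L)))
  vols <- render_volumes(cohort, atlas, voxel_noise_sd = 0, fwhm_mm = 0)
  for (s in names(vols))
    expect_equal(roi_suvmean(vols[[s]], atlas),
                 cohort$suv[match(s, cohort$subjects$subject), ],
                 tolerance = 1e-12)
  # unknown region in the cohort is fatal
  bad <- cohort
  colnames(bad$suv)[1] <- "NOPE"
  expect_error(render_volumes(bad, atlas), "NOPE")
})

test_that("voxel noise leaves ROI means unbiased within the standard-error bound", {
  atlas <- fixture_atlas()
  cohort <- simulate_cohort(null_design(atlas, seed = 3, n = c(4L, 4L)))
  set.seed(99)
  vols <- render_volumes(cohort, atlas, voxel_noise_sd = 0.05, fwhm_mm = 0)
  nvox <- atlas$voxel_counts[1]   # fixture regions are equally sized
  bound <- 3 * 0.05 / sqrt(nvox)
  devs <- vapply(names(vols), function(s)
    mean(abs(roi_suvmean(vols[[s]], atlas) -
               cohort$suv[match(s, cohort$subjects$subject), ])),
    numeric(1))
  expect_true(all(devs <= bound))
})

test_that("smoothing a delta image gives the closed-form Gaussian profile", {
  vol <- array(0, dim = c(21, 21, 21))
  vol[11, 11, 11] <- 1
  vox_mm <- c(3, 3, 3)
  sm <- metaconn:::smooth_gaussian(vol, fwhm_mm = 10, voxel_mm = vox_mm)
  sigma_vox <- fwhm_to_sigma(10) / 3
  expect_equal(fwhm_to_sigma(10), 4.2466, tolerance = 1e-4)
  # one-voxel-offset ratio along each axis: exp(-1 / (2 sigma^2))
  ratio <- exp(-1 / (2 * sigma_vox^2))
  expect_equal(sm[12, 11, 11] / sm[11, 11, 11], ratio, tolerance = 1e-10)
  expect_equal(sm[11, 12, 11] / sm[11, 11, 11], ratio, tolerance = 1e-10)
  expect_equal(sm[11, 11, 12] / sm[11, 11, 11], ratio, tolerance = 1e-10)
  # separability: diagonal neighbour is the product of axis ratios
  expect_equal(sm[12, 12, 11] / sm[11, 11, 11], ratio^2, tolerance = 1e-10)
  # mass is conserved away from the boundary
  expect_equal(sum(sm), 1, tolerance = 1e-6)
})

test_that("an unrepairable covariance is rejected, a repairable one is repaired with a warning", {
  # in a 3-region block, rho = 0.9 equicorrelation plus an antagonistic
  # -0.9 edge override is not a valid correlation matrix; nearPD repairs it
  atlas <- make_fixture_atlas(c(24, 24, 24), 3, seed = 7)
  d <- null_design(atlas, rho = 0.9, n = c(10L, 10L), seed = 1)
  d$edge_effects <- data.frame(region_i = "VIS_1", region_j = "VIS_2",
                               group = "CSVD", rho = -0.9)
  expect_warning(simulate_cohort(d), "nearest-PD")
})
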