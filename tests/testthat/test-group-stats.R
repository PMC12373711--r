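test_that("pooled t matches the textbook formula and degenerates correctly", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4)
  # independent hand computation of the pooled statistic
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), length(x) + length(y) - 2)
  got <- two_sample_t(x, y, "pooled")
  expect_equal(got$t, t_oracle, tolerance = 1e-12)
  expect_equal(got$df, 5)
  expect_equal(got$p, p_oracle, tolerance = 1e-12)

  same <- two_sample_t(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(two_sample_t(c(1), c(1, 2)), "at least 2")
  expect_error(two_sample_t(c(2, 2, 2), c(2, 2)), "degenerate")

  welch <- two_sample_t(x, y, "welch")
  expect_lt(welch$df, 5)
})

test_that("the two-sample t is calibrated on a null at the study's group sizes", {
  set.seed(2024)
  n_rep <- 2000L
  rej <- 0L
  for (r in seq_len(n_rep)) {
    x <- stats::rnorm(174, 1.0, 0.08)
    y <- stats::rnorm(206, 1.0, 0.08)
    rej <- rej + (two_sample_t(x, y)$p < 0.05)
  }
  expect_gte(rej / n_rep, 0.04)
  expect_lte(rej / n_rep, 0.06)
})

test_that("Cohen's D reproduces published worked examples and is signed", {
  expect_equal(cohens_d(0.862, 0.079, 174, 0.814, 0.083, 206), 0.59,
               tolerance = 0.01)
  expect_equal(cohens_d(1.109, 0.070, 174, 1.080, 0.064, 206), 0.43,
               tolerance = 0.01)
  expect_equal(cohens_d(1, 0.1, 10, 1, 0.1, 10), 0)
  expect_lt(cohens_d(0.9, 0.05, 50, 1.0, 0.05, 50), 0)
  expect_error(cohens_d(1, 0, 10, 1, 0.1, 10), "positive")
})

test_that("chi-square on 2x2 tables matches closed form, Fisher enumeration, and Yates monotonicity", {
  # identical proportions: no association
  none <- chi_square_2x2(rbind(c(30, 70), c(60, 140)))
  expect_equal(none$statistic, 0, tolerance = 1e-12)
  expect_equal(none$p, 1)

  # hypertension-style counts: Pearson statistic against the closed form
  tab <- rbind(c(52, 122), c(39, 167))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat_oracle <- sum((tab - expected)^2 / expected)
  got <- chi_square_2x2(tab, "none")
  expect_equal(got$statistic, stat_oracle, tolerance = 1e-10)
  expect_equal(got$p, stats::pchisq(stat_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # exact variant against an explicit hypergeometric enumeration
  exact <- chi_square_2x2(tab, "exact")
  a_range <- 0:min(sum(tab[1, ]), colSums(tab)[1])
  probs <- stats::dhyper(a_range, colSums(tab)[1], colSums(tab)[2],
                         sum(tab[1, ]))
  p_enum <- sum(probs[probs <= stats::dhyper(tab[1, 1], colSums(tab)[1],
                                             colSums(tab)[2],
                                             sum(tab[1, ])) * (1 + 1e-7)])
  expect_equal(exact$p, p_enum, tolerance = 1e-9)

  # Yates correction never increases the statistic
  set.seed(7)
  for (i in 1:20) {
    rtab <- matrix(stats::rpois(4, 40) + 1, 2, 2)
    expect_lte(chi_square_2x2(rtab, "yates")$statistic,
               chi_square_2x2(rtab, "none")$statistic + 1e-12)
  }

  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("BH-FDR matches the hand-applied step-up rule and its invariants", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  p <- stats::runif(50)
  q <- fdr_bh(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # order-preserving: q sorted by p is non-decreasing
  expect_false(is.unsorted(q[order(p)]))
  # reapplication can only raise q-values; constant vectors are fixed points
  expect_true(all(fdr_bh(q) >= q))
  expect_equal(fdr_bh(rep(0.4, 8)), rep(0.4, 8))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("region comparison is calibrated, recovers effects, and nulls exact duplicates", {
  atlas <- fixture_atlas()
  # duplicated group: every statistic collapses to the null
  cohort <- simulate_cohort(null_design(atlas, seed = 31, n = c(20L, 20L)))
  dup <- manual_cohort(rbind(group_suv(cohort, "CSVD"),
                             group_suv(cohort, "CSVD")), 20, 20)
  rc <- region_comparison(dup, atlas)
  expect_true(all(rc$p == 1))
  expect_true(all(rc$cohens_d == 0))
  expect_true(all(rc$q >= rc$p))
  expect_true(all(sign(rc$t) == sign(rc$mean1 - rc$mean2)))

  # shape: 7 whole-network rows + 14 region rows
  expect_equal(sum(is.na(rc$region)), 7L)
  expect_equal(sum(!is.na(rc$region)), 14L)

  # parameter recovery at published effect scale: group means 0.862/0.814,
  # SDs ~0.08 -> generating d ~0.59; the recovered D must track it
  b <- flat_baselines(atlas, mean = 0.814, sd = 0.081)
  ds <- vapply(1:100, function(r) {
    d <- cohort_design(atlas, baseline_means = b$means, baseline_sds = b$sds,
                       network_correlation = 0.3,
                       point_effects = data.frame(region = "SMN_2",
                                                  group = "CSVD",
                                                  delta = 0.048),
                       covariate_specs = NULL, seed = 5000L + r)
    co <- simulate_cohort(d)
    rc <- region_comparison(co, atlas)
    rc$cohens_d[!is.na(rc$abbreviation) & rc$abbreviation == "SMN_2"]
  }, numeric(1))
  gen_d <- 0.048 / 0.081
  expect_lt(abs(mean(ds) - gen_d), 0.15)
})

test_that("voxelwise comparison reduces to the scalar t and is calibrated under the null", {
  atlas <- fixture_atlas()
  cohort <- simulate_cohort(null_design(atlas, seed = 17, n = c(8L, 9L)))
  vols <- render_volumes(cohort, atlas)
  groups <- cohort$subjects$group

  # single-voxel mask: identical to two_sample_t on that voxel
  vox <- which(atlas$label_volume == 1L)[1]
  mask1 <- array(FALSE, dim = dim(atlas$label_volume)); mask1[vox] <- TRUE
  sm <- voxelwise_comparison(vols, groups, mask1,
                             group_labels = cohort$group_labels)
  vals <- vapply(vols, function(v) v[vox], numeric(1))
  ht <- two_sample_t(vals[groups == "CSVD"], vals[groups == "HC"])
  expect_equal(sm$t[vox], ht$t, tolerance = 1e-10)
  expect_equal(sm$df, ht$df)

  # null calibration: median suprathreshold count after FDR is 0
  counts <- vapply(1:20, function(r) {
    co <- simulate_cohort(null_design(atlas, seed = 900L + r,
                                      n = c(10L, 10L)))
    vv <- render_volumes(co, atlas, voxel_noise_sd = 0.02)
    s <- voxelwise_comparison(vv, co$subjects$group,
                              network_mask(atlas, "visual"),
                              group_labels = co$group_labels)
    sum(s$sig_pos) + sum(s$sig_neg)
  }, numeric(1))
  expect_equal(stats::median(counts), 0)

  expect_error(voxelwise_comparison(vols[1:2], groups[1:2], mask1),
               "2 subjects")
})

test_that("a painted region effect is recovered voxelwise with the right sign", {
  atlas <- fixture_atlas()
  b <- flat_baselines(atlas, mean = 1, sd = 0.08)
  hits <- vapply(1:10, function(r) {
    d <- cohort_design(atlas, baseline_means = b$means, baseline_sds = b$sds,
                       network_correlation = 0,
                       point_effects = data.frame(region = "VIS_1",
                                                  group = "CSVD",
                                                  delta = 0.6 * 0.08),
                       covariate_specs = NULL, n_per_group = c(100L, 100L),
                       seed = 700L + r)
    co <- simulate_cohort(d)
    vv <- render_volumes(co, atlas)
    s <- voxelwise_comparison(vv, co$subjects$group,
                              network_mask(atlas, "visual"),
                              group_labels = co$group_labels)
    in_region <- atlas$label_volume == 1L
    mean(s$sig_pos[in_region])
  }, numeric(1))
  expect_gte(mean(hits >= 0.8), 0.8)
})

test_that("cluster extraction recovers painted blobs, centroids, and handles empties", {
  affine <- diag(c(-3, 3, 3, 1)); affine[1:3, 4] <- c(30, -30, -30)
  dims <- c(20, 20, 20)

  expect_equal(nrow(extract_clusters(array(1, dims),
                                     array(FALSE, dims), affine)), 0L)

  # single voxel: centroid is its world coordinate
  tarr <- array(NA_real_, dims)
  sig <- array(FALSE, dims)
  tarr[4, 5, 6] <- 3.5; sig[4, 5, 6] <- TRUE
  cl <- extract_clusters(tarr, sig, affine)
  expect_equal(cl$cluster_size, 1L)
  world <- affine %*% c(3, 4, 5, 1)
  expect_equal(c(cl$x, cl$y, cl$z), world[1:3])
  expect_equal(cl$peak_t, 3.5)

  # two disjoint painted blobs of 25 and 58 voxels, opposite signs
  tarr <- array(NA_real_, dims); sig <- array(FALSE, dims)
  blob1 <- as.matrix(expand.grid(2:6, 2:6, 2))             # 25 voxels
  idx1 <- blob1[, 1] + dims[1] * (blob1[, 2] - 1) +
    dims[1] * dims[2] * (blob1[, 3] - 1)
  set.seed(12)
  # 58 = 27 + 31: a 3x3x3 cube plus a 31-voxel slab, 26-connected
  blob2a <- as.matrix(expand.grid(12:14, 12:14, 12:14))
  blob2b <- as.matrix(expand.grid(12:17, 12:17, 15))[1:31, ]
  blob2 <- rbind(blob2a, blob2b)
  idx2 <- blob2[, 1] + dims[1] * (blob2[, 2] - 1) +
    dims[1] * dims[2] * (blob2[, 3] - 1)
  tarr[idx1] <- 4; tarr[idx1[1]] <- 4.6
  tarr[idx2] <- -3.7; tarr[idx2[5]] <- -4.2
  sig[c(idx1, idx2)] <- TRUE
  cl <- extract_clusters(tarr, sig, affine)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$cluster_size, c(25L, 58L))
  pos <- cl[cl$sign == "positive", ]
  expect_equal(pos$cluster_size, 25L)
  expect_equal(pos$peak_t, 4.6)
  centroid0 <- colMeans(blob1) - 1
  world <- affine %*% c(centroid0, 1)
  expect_equal(c(pos$x, pos$y, pos$z), world[1:3], tolerance = 1.5)
  neg <- cl[cl$sign == "negative", ]
  expect_equal(neg$peak_t, -4.2)
  cent2 <- affine %*% c(colMeans(blob2) - 1, 1)
  expect_equal(c(neg$x, neg$y, neg$z), cent2[1:3], tolerance = 1.5)
})

test_that("voxelwise t equals region t when volumes are regionwise constant", {
  atlas <- fixture_atlas()
  cohort <- simulate_cohort(null_design(atlas, seed = 55, n = c(6L, 7L)))
  vols <- render_volumes(cohort, atlas)   # regionwise-constant by design
  m <- network_mask(atlas, "limbic")
  sm <- voxelwise_comparison(vols, cohort$subjects$group, m,
                             group_labels = cohort$group_labels)
  rc <- region_comparison(cohort, atlas)
  for (a in c("LIM_1", "LIM_2")) {
    id <- atlas$regions$id[atlas$regions$abbreviation == a]
    t_vox <- unique(round(sm$t[atlas$label_volume == id], 10))
    t_reg <- rc$t[!is.na(rc$abbreviation) & rc$abbreviation == a]
    expect_equal(length(t_vox), 1L)
    expect_equal(t_vox, round(t_reg, 10))
  }
})
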