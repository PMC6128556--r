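# Synthetic-cohort generator: masks, planted patterns, determinism and
# signal/null construction.

test_that("ellipsoid mask matches brute-force voxel enumeration", {
  # degenerate ellipsoid: only the centre voxel
  m <- make_ellipsoid_mask(c(3, 3, 3), c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(sum(m), 1)
  expect_true(m[2, 2, 2])

  # unit radii: centre + 6 face neighbours, cross-checked by enumeration
  m <- make_ellipsoid_mask(c(3, 3, 3), c(2, 2, 2), c(1, 1, 1))
  brute <- 0L
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    if ((i - 2)^2 + (j - 2)^2 + (k - 2)^2 <= 1) brute <- brute + 1L
  }
  expect_equal(sum(m), brute)
  expect_equal(sum(m), 7)

  # radii larger than the grid: the full grid is in the mask
  expect_equal(sum(make_ellipsoid_mask(c(3, 3, 3), c(2, 2, 2), c(10, 10, 10))), 27)

  expect_error(make_ellipsoid_mask(c(3, 3, 3), c(2, 2, 2), c(0, 1, 1)), "positive")
})

test_that("planted patterns have the configured ROI geometry", {
  cfg1 <- cohort_config(pattern_rois = list(
    list(center = c(8, 10, 12), radii = c(3, 3, 3), sign = 1)))
  p1 <- plant_pattern(cfg1)
  expect_equal(min(p1$volume), 0)
  expect_equal(max(p1$volume), 1)

  cfg2 <- cohort_config()  # default: one +1 and one -1 disjoint ROI
  p2 <- plant_pattern(cfg2)
  n_pos <- sum(make_ellipsoid_mask(cfg2$grid_dims, c(8, 10, 12), c(3, 3, 3)))
  n_neg <- sum(make_ellipsoid_mask(cfg2$grid_dims, c(17, 19, 13), c(3, 3, 3)))
  expect_equal(sum(p2$volume), n_pos - n_neg)

  cfg0 <- cohort_config(pattern_rois = list())
  expect_true(all(plant_pattern(cfg0)$volume == 0))

  # overlapping ROIs with conflicting signs are rejected
  cfg_bad <- cohort_config(pattern_rois = list(
    list(center = c(10, 12, 12), radii = c(4, 4, 4), sign = 1),
    list(center = c(11, 12, 12), radii = c(4, 4, 4), sign = -1)))
  expect_error(plant_pattern(cfg_bad), "conflicting signs")
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_subjects = 2), "at least 3")
  expect_error(cohort_config(score_noise_sd = 0), "positive")
  expect_error(cohort_config(signal_beta = -1), "non-negative")
  expect_error(cohort_config(loadings = rep(2, 17)), "\\[-1, 1\\]")
  expect_error(cohort_config(pattern_rois = list(
    list(center = c(2, 2, 2), radii = c(5, 5, 5), sign = 1))), "fit inside")
  expect_error(cohort_config(pattern_rois = list(
    list(center = c(8, 10, 12), radii = c(2, 2, 2), sign = 1),
    list(center = c(16, 18, 13), radii = c(2, 2, 2), sign = 1))),
    "positive and a negative")
  expect_error(cohort_config(loadings = matrix(0.5, 17, 4)), "3 latent factors")
})

test_that("identical configurations give bit-identical cohorts", {
  a <- simulate_cohort(cohort_config(seed = 11))
  b <- simulate_cohort(cohort_config(seed = 11))
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$scores, b$scores)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$g, b$g)
})

test_that("null cohorts decouple scores from the latent factor", {
  co <- simulate_cohort(null_cohort_config(seed = 5))
  rs <- apply(as.matrix(co$scores[, -1]), 2, cor, y = co$g[, 1])
  expect_true(all(abs(rs) < 0.6))
})

test_that("a strong planted signal shows up voxelwise inside the ROI", {
  # signal amplitude 10x the (small) voxel noise SD
  co <- simulate_cohort(cohort_config(volume_noise_sd = 2, signal_beta = 20,
                                      seed = 3))
  roi <- which(co$pattern$volume > 0)[c(1, 20, 50)]
  for (v in roi) {
    idx <- arrayInd(v, dim(co$pattern$volume))
    vals <- co$volumes[idx[1], idx[2], idx[3], ]
    expect_gt(abs(cor(vals, co$g[, 1])), 0.9)
  }
  # negative-ROI voxels anticorrelate with g
  neg <- which(co$pattern$volume < 0)[1]
  idx <- arrayInd(neg, dim(co$pattern$volume))
  expect_lt(cor(co$volumes[idx[1], idx[2], idx[3], ], co$g[, 1]), -0.9)
})

test_that("uptake values stay positive, flooring with a warning if needed", {
  co <- simulate_cohort(cohort_config(seed = 1))
  expect_true(all(co$volumes > 0))
  expect_warning(
    simulate_cohort(cohort_config(baseline_level = 1, volume_noise_sd = 30,
                                  seed = 1)),
    "floored")
})

test_that("multi-factor cohorts couple each factor to its own pattern", {
  loadings <- cbind(c(rep(0.8, 9), rep(0, 8)), c(rep(0, 9), rep(0.8, 8)))
  rois <- list(
    list(center = c(8, 10, 12), radii = c(3, 3, 3), sign = 1, factor = 1),
    list(center = c(17, 19, 13), radii = c(3, 3, 3), sign = -1, factor = 1),
    list(center = c(12, 20, 12), radii = c(2, 2, 2), sign = 1, factor = 2),
    list(center = c(12, 8, 12), radii = c(2, 2, 2), sign = -1, factor = 2))
  co <- simulate_cohort(cohort_config(loadings = loadings, pattern_rois = rois,
                                      seed = 9))
  expect_equal(ncol(co$g), 2)
  expect_length(co$pattern$volumes, 2)
  # factor-2 ROI responds to g2, not (strongly) to g1
  roi2 <- co$pattern$volumes[[2]] > 0
  m2 <- apply(co$volumes, 4, function(v) mean(v[roi2]))
  expect_gt(cor(m2, co$g[, 2]), 0.8)
})
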