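# LOOCV, permutation significance and fold-averaged weight maps.

test_that("pearson_r matches the hand formula and rejects degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(-1, -2, -3)), -1)
  # hand formula: sum(dev products) / sqrt(sum sq * sum sq)
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 100)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), r_hand, tolerance = 1e-12)
  expect_equal(r_hand, 0.78503, tolerance = 1e-4)
  expect_equal(pearson_r(a, b), pearson_r(b, a))
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("LOOCV equals manually assembled leave-one-out fits", {
  set.seed(1)
  x <- matrix(rnorm(4 * 6), 4, 6)
  y <- rnorm(4)
  cv <- loocv(x, y, sigma2 = 0.1)
  manual <- vapply(1:4, function(i) {
    fit <- linear_gp(x[-i, , drop = FALSE], y[-i], sigma2 = 0.1)
    predict(fit, x[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(cv$predicted, manual, tolerance = 1e-10)
  manual_w <- vapply(1:4, function(i)
    coef(linear_gp(x[-i, , drop = FALSE], y[-i], sigma2 = 0.1)), numeric(6))
  expect_equal(cv$fold_weights, manual_w, tolerance = 1e-10)

  expect_error(loocv(x, rep(1, 4)), "constant")
  expect_error(loocv(x[1:3, ], y[1:3]), "at least 4")
})

test_that("fold-safe LOOCV residualizes inside each training fold", {
  co <- strong_cohort(seed = 42)
  ages <- co$demographics$age
  pp <- preprocess_fixture(co, residualize = FALSE)
  cv <- loocv(pp$features, co$g[, 1], fold_safe = TRUE, ages = ages)
  # manual first fold
  x <- pp$features$values
  tr <- 2:16
  dm <- cbind(1, ages[tr])
  beta <- qr.coef(qr(dm), x[tr, ])
  xtr <- x[tr, ] - dm %*% beta
  xte <- x[1, , drop = FALSE] - cbind(1, ages[1]) %*% beta
  fit <- linear_gp(xtr, co$g[tr, 1], sigma2 = 0.001)
  expect_equal(cv$predicted[1], unname(predict(fit, xte)), tolerance = 1e-8)
  # stage guard: fold-safe needs scaled features, plain LOOCV residualized
  expect_error(loocv(pp$features, co$g[, 1]), "residualized")
  ppr <- preprocess_fixture(co)
  expect_error(loocv(ppr$features, co$g[, 1], fold_safe = TRUE, ages = ages),
               "scaled")
  expect_error(loocv(pp$features, co$g[, 1], fold_safe = TRUE), "ages")
})

test_that("a strong planted signal is predicted accurately", {
  co <- strong_cohort(seed = 42)
  pp <- preprocess_fixture(co, residualize = FALSE)
  cv <- loocv(pp$features, co$g[, 1], fold_safe = TRUE,
              ages = co$demographics$age)
  expect_gte(cv$pearson_r, 0.8)
})

test_that("permutation p-values follow the count/B convention deterministically", {
  # dominant rank-1 structure makes the targets near-perfectly predictable
  set.seed(2)
  y <- rnorm(8)
  x <- y %*% t(rnorm(20)) + matrix(rnorm(8 * 20, sd = 0.05), 8, 20)
  p1 <- permutation_test(x, y, B = 50, seed = 99)
  p2 <- permutation_test(x, y, B = 50, seed = 99)
  expect_identical(p1$null_rs, p2$null_rs)
  expect_identical(p1$p_value, p2$p_value)

  # enlarging B keeps earlier draws (counter-based child seeds)
  p3 <- permutation_test(x, y, B = 100, seed = 99)
  expect_identical(p3$null_rs[1:50], p1$null_rs)

  # p on the count/B grid
  expect_true(p3$p_value * p3$B == round(p3$p_value * p3$B))
  # observed beats every null here: reported as p < 1/B
  expect_equal(p1$p_value, 0)
  expect_match(p1$p_label, "p < 0.02")
  expect_error(permutation_test(x, y, B = 0), "at least 1")

  # two-sided option counts |r|
  pt2 <- permutation_test(x, y, B = 20, seed = 5, alternative = "two.sided")
  expect_equal(pt2$p_value, mean(abs(pt2$null_rs) >= abs(pt2$observed_r)))
})

test_that("null cohorts give unremarkable permutation p-values", {
  ps <- vapply(1:10, function(s) {
    co <- simulate_cohort(null_cohort_config(seed = 300 + s))
    pp <- preprocess_fixture(co)
    pca <- neuropsych_pca(co$scores)
    permutation_test(pp$features, pca$scores[, 1], B = 39,
                     seed = 300 + s)$p_value
  }, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_gt(mean(ps), 0.2)   # no systematic inflation
})

test_that("prediction accuracy grows with the planted signal strength", {
  mean_r <- vapply(c(0, 2, 8), function(beta) {
    rs <- vapply(1:6, function(s) {
      co <- simulate_cohort(cohort_config(grid_dims = c(20, 24, 20),
                                          signal_beta = beta,
                                          seed = 500 + s))
      pp <- preprocess_fixture(co, residualize = FALSE)
      loocv(pp$features, co$g[, 1], fold_safe = TRUE,
            ages = co$demographics$age, compute_weights = FALSE)$pearson_r
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("weight maps average folds and respect the mask", {
  # identical fold vectors pass through; simple two-fold average
  vi <- cbind(c(1, 2), 1, 1)
  expect_equal(average_weight_map(cbind(c(1, 3), c(3, 1)), vi, c(2, 1, 1)),
               array(c(2, 2), c(2, 1, 1)))
  w <- c(0.5, -0.25)
  expect_equal(average_weight_map(cbind(w, w, w), vi, c(3, 1, 1)),
               array(c(w, 0), c(3, 1, 1)))
  expect_error(average_weight_map(matrix(1, 3, 2), vi, c(2, 1, 1)),
               "does not match")

  # recovery: the averaged map aligns with the planted pattern
  co <- strong_cohort(seed = 42)
  pp <- preprocess_fixture(co, residualize = FALSE)
  cv <- loocv(pp$features, co$g[, 1], fold_safe = TRUE,
              ages = co$demographics$age)
  wm <- average_weight_map(cv, pp$features$voxel_index, dim(pp$mask))
  expect_true(all(wm[!pp$mask] == 0))
  truth <- downsample_by_two(co$pattern$volume)
  expect_gte(cosine_similarity(wm[pp$mask], truth[pp$mask]), 0.5)

  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})
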