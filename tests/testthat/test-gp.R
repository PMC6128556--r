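# Linear-kernel GP regression: Gram computation, dual fit, prediction,
# primal weights, marginal likelihood and noise tuning.

test_that("the linear-kernel Gram matrix is exact and PSD", {
  expect_equal(compute_gram(diag(2)), diag(2))
  expect_equal(compute_gram(matrix(c(1, 3, 2, 4), 2, 2)),
               matrix(c(5, 11, 11, 25), 2, 2))
  set.seed(1)
  x <- matrix(rnorm(5 * 12), 5, 12)
  k <- compute_gram(x)
  expect_equal(k, t(k), tolerance = 1e-12)
  expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8 * sum(diag(k)))
  expect_error(compute_gram(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("the dual fit solves (K + sigma2 I) alpha = y - ybar", {
  # constant targets: alpha = 0
  fit0 <- linear_gp(matrix(rnorm(12), 4, 3), rep(2, 4))
  expect_equal(fit0$alpha, rep(0, 4))

  # hand-solvable 2x2 identity case
  fit <- linear_gp(diag(2), c(1, -1), sigma2 = 0.001)
  expect_equal(fit$y_mean, 0)
  expect_equal(fit$alpha, c(1, -1) / 1.001, tolerance = 1e-12)

  # seeded wide problem vs explicit matrix-inverse oracle
  set.seed(2)
  x <- matrix(rnorm(8 * 50), 8, 50); y <- rnorm(8)
  fit <- linear_gp(x, y, sigma2 = 0.05)
  k <- x %*% t(x)
  alpha_oracle <- solve(k + 0.05 * diag(8)) %*% (y - mean(y))
  expect_equal(fit$alpha, drop(alpha_oracle), tolerance = 1e-10)
  # model invariant
  expect_lt(max(abs((k + 0.05 * diag(8)) %*% fit$alpha - (y - mean(y)))),
            1e-8 * max(abs(y)))
})

test_that("prediction interpolates at sigma2 = 0 and equals the primal ridge path", {
  set.seed(3)
  x <- matrix(rnorm(4 * 10), 4, 10); y <- rnorm(4)
  fit <- linear_gp(x, y, sigma2 = 0)
  expect_equal(predict(fit, x), y, tolerance = 1e-8)

  # alpha = 0 predicts the target mean everywhere
  fit0 <- linear_gp(x, rep(1.5, 4))
  expect_equal(predict(fit0, matrix(rnorm(20), 2, 10)), rep(1.5, 2))

  # dual/primal equivalence on a seeded wide problem
  set.seed(4)
  xtr <- matrix(rnorm(8 * 50), 8, 50); ytr <- rnorm(8)
  xte <- matrix(rnorm(50), 1, 50)
  s2 <- 0.01
  fit <- linear_gp(xtr, ytr, sigma2 = s2)
  w_dual <- t(xtr) %*% solve(xtr %*% t(xtr) + s2 * diag(8)) %*% (ytr - mean(ytr))
  w_primal <- solve(t(xtr) %*% xtr + s2 * diag(50)) %*% t(xtr) %*% (ytr - mean(ytr))
  expect_equal(drop(w_dual), drop(w_primal), tolerance = 1e-8)
  expect_equal(predict(fit, xte), mean(ytr) + drop(xte %*% w_primal),
               tolerance = 1e-8)
  expect_error(predict(fit, matrix(0, 1, 49)), "columns")
})

test_that("primal weights reproduce the kernel prediction path", {
  fit <- linear_gp(diag(2), c(1, -1), sigma2 = 0.5)
  expect_equal(coef(fit), fit$alpha)   # X = I

  set.seed(5)
  x <- matrix(rnorm(6 * 40), 6, 40); y <- rnorm(6)
  fit <- linear_gp(x, y, sigma2 = 0.01)
  w <- coef(fit)
  xnew <- matrix(rnorm(3 * 40), 3, 40)
  expect_equal(predict(fit, xnew), fit$y_mean + drop(xnew %*% w),
               tolerance = 1e-10)
})

test_that("log marginal likelihood matches closed form and a dense oracle", {
  # K = 0 (all-zero features), sigma2 = 1, y = (a, -a): -a^2 - log(2*pi)
  a <- 0.7
  expect_equal(log_marginal_likelihood(matrix(0, 2, 3), c(a, -a), 1),
               -a^2 - log(2 * pi), tolerance = 1e-12)

  set.seed(6)
  x <- matrix(rnorm(6 * 20), 6, 20); y <- rnorm(6)
  # translation invariance through target centring
  expect_equal(log_marginal_likelihood(x, y, 0.3),
               log_marginal_likelihood(x, y + 100, 0.3), tolerance = 1e-8)
  # dense oracle with explicit inverse and determinant
  k <- x %*% t(x); a_mat <- k + 0.3 * diag(6); yc <- y - mean(y)
  oracle <- -0.5 * t(yc) %*% solve(a_mat) %*% yc -
    0.5 * log(det(a_mat)) - 3 * log(2 * pi)
  expect_equal(log_marginal_likelihood(x, y, 0.3), drop(oracle),
               tolerance = 1e-8)
  expect_error(log_marginal_likelihood(matrix(0, 1, 2), 1, 1), "at least 2")
})

test_that("noise tuning maximizes the evidence", {
  # pure-noise targets with zero features: optimum is the target variance
  set.seed(7)
  y <- rnorm(200, sd = 2)
  s2_hat <- optimize_noise(matrix(0, 200, 2), y, bounds = c(1e-3, 50))
  expect_equal(s2_hat, mean((y - mean(y))^2), tolerance = 0.2)

  set.seed(8)
  x <- matrix(rnorm(8 * 15), 8, 15); yy <- rnorm(8)
  s2_hat <- optimize_noise(x, yy, bounds = c(1e-4, 10), tol = 1e-4)
  ev <- function(s2) log_marginal_likelihood(x, yy, s2)
  expect_gte(ev(s2_hat), ev(1e-4) - 1e-6)
  expect_gte(ev(s2_hat), ev(10) - 1e-6)
  # grid-search oracle
  grid <- exp(seq(log(1e-4), log(10), length.out = 1e4))
  s2_grid <- grid[which.max(vapply(grid, ev, numeric(1)))]
  expect_equal(log(s2_hat), log(s2_grid), tolerance = 2e-3)
  expect_error(optimize_noise(x, yy, bounds = c(0, 1)), "positive")
})

test_that("shrinkage is monotone in the noise variance", {
  set.seed(9)
  x <- matrix(rnorm(10 * 30), 10, 30); y <- rnorm(10)
  norms <- t(vapply(c(0.01, 0.1, 1, 10), function(s2) {
    fit <- linear_gp(x, y, sigma2 = s2)
    c(sqrt(sum(fit$alpha^2)), sqrt(sum(coef(fit)^2)))
  }, numeric(2)))
  expect_true(all(diff(norms[, 1]) <= 0))
  expect_true(all(diff(norms[, 2]) <= 0))
})

test_that("predictions agree with an independent GP implementation", {
  skip_if_not_installed("kernlab")
  set.seed(10)
  x <- matrix(rnorm(10 * 25), 10, 25)
  y <- rnorm(10); yc <- y - mean(y)   # kernlab::gausspr does not centre
  fit_ours <- linear_gp(x, yc, sigma2 = 0.05)
  fit_k <- kernlab::gausspr(x, yc, kernel = "vanilladot", var = 0.05,
                            scaled = FALSE)
  xte <- matrix(rnorm(4 * 25), 4, 25)
  expect_equal(predict(fit_ours, xte), drop(kernlab::predict(fit_k, xte)),
               tolerance = 1e-6)
})

test_that("model methods are coherent", {
  set.seed(11)
  x <- matrix(rnorm(6 * 12), 6, 12); y <- rnorm(6)
  fit <- linear_gp(x, y, sigma2 = 0.1)
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_s3_class(summary(fit), "summary.linear_gp")
  expect_output(print(fit), "Gaussian process")
  expect_output(print(summary(fit)), "log marginal")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(6, 3))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), log_marginal_likelihood(x, y, 0.1))
  # evidence-optimized fit stores the tuned sigma2
  fit_opt <- linear_gp(x, y, optimize = TRUE, bounds = c(1e-4, 10))
  expect_gte(log_marginal_likelihood(x, y, fit_opt$sigma2),
             log_marginal_likelihood(x, y, 0.1) - 1e-8)
})
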