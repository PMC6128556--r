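#' Linear-kernel Gram matrix
#'
#' Computes the Gram (kernel) matrix \eqn{K = X X^T} for the linear
#' ("vanilla") kernel \eqn{k(x, x') = x \cdot x'}. With this kernel,
#' Gaussian-process regression is equivalent to Bayesian linear (ridge)
#' regression, which is what makes primal voxel weight maps recoverable
#' from the dual solution.
#'
#' @param x Numeric matrix, subjects in rows and features (voxels) in
#'   columns. All entries must be finite.
#' @return A symmetric \code{n x n} positive semi-definite matrix.
#' @examples
#' compute_gram(diag(2))
#' @export
compute_gram <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("feature matrix contains non-finite entries")
  k <- tcrossprod(x)
  (k + t(k)) / 2
}

## Cholesky solve with a one-shot jitter fallback for numerically
## semi-definite Gram matrices. Returns list(solution, log_det, jitter).
.chol_solve <- function(a, b) {
  ch <- tryCatch(chol(a), error = function(e) NULL)
  jitter <- 0
  if (is.null(ch)) {
    jitter <- 1e-10 * sum(diag(a)) / nrow(a)
    if (jitter <= 0) jitter <- 1e-12
    ch <- tryCatch(chol(a + diag(jitter, nrow(a))), error = function(e) NULL)
    if (is.null(ch)) {
      stop("Gram matrix plus noise variance is singular; ",
           "increase sigma2 or check the features")
    }
    warning(sprintf("Gram matrix not positive definite; added jitter %g", jitter))
  }
  list(solution = backsolve(ch, forwardsolve(t(ch), b)),
       log_det = 2 * sum(log(diag(ch))),
       jitter = jitter)
}

#' Fit a linear-kernel Gaussian-process regression model
#'
#' Fits GP regression with the linear kernel in its dual (Gram) form:
#' the targets are centred by their training mean \eqn{\bar y} and the
#' dual coefficients solve \eqn{(K + \sigma^2 I)\alpha = y - \bar y}
#' with \eqn{K = X X^T}. This is the standard formulation for wide
#' neuroimaging feature matrices where the number of voxels far exceeds
#' the number of subjects: all linear algebra is \code{n x n}.
#'
#' The noise variance defaults to 0.001 (a conventional setting for
#' linear-kernel GP regression on globally scaled metabolic features).
#' With \code{optimize = TRUE} it is instead tuned by type-II maximum
#' likelihood, maximising the log marginal likelihood over
#' \eqn{\log\sigma^2} within \code{bounds}.
#'
#' @param x Numeric matrix of training features, subjects in rows.
#' @param y Numeric vector of training targets (one per subject).
#' @param sigma2 Noise variance \eqn{\sigma^2 \ge 0}. Ignored when
#'   \code{optimize = TRUE}.
#' @param optimize If \code{TRUE}, tune \code{sigma2} by type-II maximum
#'   likelihood (see \code{\link{optimize_noise}}).
#' @param bounds Search interval for \code{sigma2} when optimising.
#' @param tol Termination tolerance of the noise optimisation.
#' @return An object of class \code{"linear_gp"} with components
#'   \code{alpha} (dual coefficients), \code{sigma2}, \code{y_mean},
#'   \code{gram}, \code{x}, \code{y}.
#' @seealso \code{\link{predict.linear_gp}}, \code{\link{coef.linear_gp}},
#'   \code{\link{log_marginal_likelihood}}, \code{\link{loocv}}
#' @examples
#' fit <- linear_gp(diag(2), c(1, -1), sigma2 = 0.001)
#' coef(fit)
#' @export
linear_gp <- function(x, y, sigma2 = 0.001, optimize = FALSE,
                      bounds = c(1e-8, 1e2), tol = 0.001) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 training subjects")
  if (length(y) != n) stop("length of y must match nrow(x)")
  if (!all(is.finite(y))) stop("targets contain non-finite values")
  if (optimize) {
    sigma2 <- optimize_noise(x, y, bounds = bounds, tol = tol)
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 < 0) {
    stop("sigma2 must be a single non-negative number")
  }
  k <- compute_gram(x)
  y_mean <- mean(y)
  sol <- .chol_solve(k + diag(sigma2, n), y - y_mean)
  structure(
    list(alpha = drop(sol$solution), sigma2 = sigma2, y_mean = y_mean,
         gram = k, x = x, y = y, n = n, p = ncol(x),
         jitter = sol$jitter, call = match.call()),
    class = "linear_gp")
}

#' Predict from a linear-kernel GP model
#'
#' Predictive mean \eqn{\hat y_* = \bar y + X_* X^T \alpha}. With
#' \code{se.fit = TRUE} the predictive standard deviation of the latent
#' function, \eqn{\sqrt{k_{**} - k_*^T (K+\sigma^2 I)^{-1} k_*}}, is
#' returned as well.
#'
#' @param object A fitted \code{"linear_gp"} model.
#' @param newdata Matrix of new feature rows (same number of columns as
#'   the training features).
#' @param se.fit Also return predictive standard deviations.
#' @param ... Unused.
#' @return A numeric vector of predictions, or a list with components
#'   \code{fit} and \code{se.fit}.
#' @export
predict.linear_gp <- function(object, newdata, se.fit = FALSE, ...) {
  if (missing(newdata)) newdata <- object$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop(sprintf("newdata has %d columns but the model was trained on %d",
                 ncol(newdata), object$p))
  }
  k_star <- tcrossprod(newdata, object$x)        # m x n
  fit <- drop(object$y_mean + k_star %*% object$alpha)
  if (!se.fit) return(fit)
  a <- object$gram + diag(object$sigma2 + object$jitter, object$n)
  v <- .chol_solve(a, t(k_star))$solution
  var_f <- rowSums(newdata^2) - colSums(t(k_star) * v)
  list(fit = fit, se.fit = sqrt(pmax(var_f, 0)))
}

#' Primal voxel weights of a linear-kernel GP
#'
#' Maps the dual solution back to feature space: \eqn{w = X^T \alpha}.
#' The predictive mean satisfies \eqn{\hat y_* = \bar y + X_* w}, so
#' \code{w} is the multivariate weight map over voxels whose sign gives
#' the direction of the metabolism-score association.
#'
#' @param object A fitted \code{"linear_gp"} model.
#' @param ... Unused.
#' @return Numeric vector of length \code{p} (one weight per feature).
#' @export
coef.linear_gp <- function(object, ...) {
  drop(crossprod(object$x, object$alpha))
}

#' @export
fitted.linear_gp <- function(object, ...) {
  drop(object$y_mean + object$gram %*% object$alpha)
}

#' @export
residuals.linear_gp <- function(object, ...) {
  object$y - fitted(object)
}

#' Log marginal likelihood of a linear-kernel GP
#'
#' Evaluates the type-II (marginal) log likelihood
#' \deqn{-\tfrac12 (y-\bar y)^T (K+\sigma^2 I)^{-1} (y-\bar y)
#'       -\tfrac12 \log\det(K+\sigma^2 I) - \tfrac n2 \log 2\pi,}
#' computed through a Cholesky factorisation (no explicit inverse or
#' determinant). Targets are centred by their mean, so the value is
#' invariant to adding a constant to \code{y}.
#'
#' @inheritParams linear_gp
#' @return A single numeric value.
#' @export
log_marginal_likelihood <- function(x, y, sigma2) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 subjects")
  if (length(y) != n) stop("length of y must match nrow(x)")
  k <- compute_gram(x)
  yc <- y - mean(y)
  sol <- .chol_solve(k + diag(sigma2, n), yc)
  -0.5 * sum(yc * sol$solution) - 0.5 * sol$log_det - (n / 2) * log(2 * pi)
}

#' @export
logLik.linear_gp <- function(object, ...) {
  ll <- log_marginal_likelihood(object$x, object$y, object$sigma2)
  structure(ll, df = 1, nobs = object$n, class = "logLik")
}

#' Tune the GP noise variance by type-II maximum likelihood
#'
#' One-dimensional bounded maximisation of the log marginal likelihood
#' over \eqn{\log \sigma^2}, using golden-section/parabolic search
#' (\code{stats::optimize}). Deterministic.
#'
#' @inheritParams linear_gp
#' @param bounds Positive interval \code{c(lo, hi)} searched for
#'   \code{sigma2}.
#' @param tol Termination tolerance on \eqn{\log \sigma^2}.
#' @return The tuned noise variance.
#' @export
optimize_noise <- function(x, y, bounds = c(1e-8, 1e2), tol = 0.001) {
  if (length(bounds) != 2 || bounds[1] <= 0 || bounds[2] <= bounds[1]) {
    stop("bounds must be an increasing positive interval")
  }
  if (tol <= 0) stop("tol must be positive")
  x <- as.matrix(x)
  k <- compute_gram(x)
  yc <- y - mean(y)
  n <- length(yc)
  obj <- function(log_s2) {
    sol <- .chol_solve(k + diag(exp(log_s2), n), yc)
    -0.5 * sum(yc * sol$solution) - 0.5 * sol$log_det - (n / 2) * log(2 * pi)
  }
  opt <- stats::optimize(obj, interval = log(bounds), maximum = TRUE, tol = tol)
  exp(opt$maximum)
}

#' Simulate from the posterior predictive of a linear-kernel GP
#'
#' Draws independent samples from the per-point posterior predictive
#' distribution \eqn{N(\hat y_*, \mathrm{var}(f_*) + \sigma^2)}.
#'
#' @param object A fitted \code{"linear_gp"} model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param newdata Feature rows to simulate at (default: training rows).
#' @param ... Unused.
#' @return A matrix with \code{nsim} columns.
#' @export
simulate.linear_gp <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (missing(newdata)) newdata <- object$x
  pr <- predict(object, newdata, se.fit = TRUE)
  m <- length(pr$fit)
  sd_tot <- sqrt(pr$se.fit^2 + object$sigma2)
  matrix(stats::rnorm(m * nsim, mean = pr$fit, sd = sd_tot), nrow = m)
}

#' @export
print.linear_gp <- function(x, ...) {
  cat("Linear-kernel Gaussian process regression\n")
  cat(sprintf("  subjects: %d   features: %d\n", x$n, x$p))
  cat(sprintf("  noise variance sigma2: %g\n", x$sigma2))
  cat(sprintf("  target mean: %.4f   ||alpha||: %.4f\n",
              x$y_mean, sqrt(sum(x$alpha^2))))
  invisible(x)
}

#' @export
summary.linear_gp <- function(object, ...) {
  w <- coef(object)
  res <- residuals(object)
  out <- list(n = object$n, p = object$p, sigma2 = object$sigma2,
              y_mean = object$y_mean,
              log_marginal = as.numeric(logLik(object)),
              rmse_train = sqrt(mean(res^2)),
              weight_range = range(w))
  class(out) <- "summary.linear_gp"
  out
}

#' @export
print.summary.linear_gp <- function(x, ...) {
  cat("Linear-kernel GP regression\n")
  cat(sprintf("  n = %d subjects, p = %d features\n", x$n, x$p))
  cat(sprintf("  sigma2 = %g, log marginal likelihood = %.3f\n",
              x$sigma2, x$log_marginal))
  cat(sprintf("  training RMSE = %.4f\n", x$rmse_train))
  cat(sprintf("  primal weights in [%.4g, %.4g]\n",
              x$weight_range[1], x$weight_range[2]))
  invisible(x)
}
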