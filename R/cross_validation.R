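## Leave-one-out cross-validation of the linear-kernel GP, Pearson
## accuracy, permutation significance and fold-averaged weight maps.

#' Pearson product-moment correlation with degeneracy checks
#'
#' Thin wrapper around \code{stats::cor} that rejects the degenerate
#' cases (fewer than 3 pairs, constant vectors) which signal a broken
#' prediction rather than a meaningful accuracy.
#'
#' @param a,b Numeric vectors of equal length (at least 3).
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant vector: correlation undefined (degenerate prediction)")
  }
  stats::cor(a, b)
}

.fm_values <- function(features, require_stage = "residualized") {
  if (inherits(features, "feature_matrix")) {
    if (!features$stage %in% require_stage) {
      stop(sprintf("features must be at stage %s (got '%s')",
                   paste(sQuote(require_stage), collapse = " or "),
                   features$stage))
    }
    features$values
  } else as.matrix(features)
}

## One LOOCV pass given the full Gram matrix. Per fold the model is
## refit on the remaining n-1 subjects: the fold Gram is the submatrix
## K[-i,-i], the fold mean re-computed, and the held-out prediction is
## ybar + K[i,-i] alpha. Returns predictions and, optionally, the dual
## coefficients of every fold (for primal weight extraction).
.loocv_gram <- function(k, y, sigma2, keep_alpha = FALSE) {
  n <- length(y)
  preds <- numeric(n)
  alphas <- if (keep_alpha) vector("list", n) else NULL
  for (i in seq_len(n)) {
    tr <- seq_len(n)[-i]
    ytr <- y[tr]
    ybar <- mean(ytr)
    a <- k[tr, tr] + diag(sigma2, n - 1)
    alpha <- .chol_solve(a, ytr - ybar)$solution
    preds[i] <- ybar + sum(k[i, tr] * alpha)
    if (keep_alpha) alphas[[i]] <- alpha
  }
  list(predictions = preds, alphas = alphas)
}

#' Leave-one-out cross-validation of GP predictions
#'
#' For each subject in turn, fits the linear-kernel GP on the remaining
#' n - 1 subjects and predicts the held-out subject from their image
#' features alone. Accuracy is the Pearson correlation between observed
#' and predicted values across all subjects. Each fold's primal weight
#' vector is retained so the fold-averaged weight map can be formed.
#'
#' With \code{fold_safe = TRUE} the voxelwise age residualization is
#' refit inside every training fold (using \code{ages}) and applied to
#' the held-out subject with the training-fold coefficients, avoiding the
#' mild leakage of full-sample residualization; \code{features} must then
#' be at stage \code{"scaled"}.
#'
#' @param features A \code{"feature_matrix"} at stage
#'   \code{"residualized"} (or \code{"scaled"} when
#'   \code{fold_safe = TRUE}), or a bare numeric matrix.
#' @param y Numeric target vector (e.g. one principal-component score per
#'   subject); must not be constant.
#' @param sigma2 GP noise variance (default 0.001).
#' @param optimize Tune \code{sigma2} by type-II maximum likelihood
#'   within each training fold.
#' @param fold_safe Refit age residualization per fold.
#' @param ages Subject ages (required when \code{fold_safe = TRUE}).
#' @param compute_weights Retain per-fold primal weight vectors.
#' @param bounds,tol Passed to \code{\link{optimize_noise}}.
#' @return An object of class \code{"cv_result"}: observed and predicted
#'   values in subject order, \code{pearson_r}, and (optionally)
#'   \code{fold_weights}, a voxels x folds matrix.
#' @export
loocv <- function(features, y, sigma2 = 0.001, optimize = FALSE,
                  fold_safe = FALSE, ages = NULL, compute_weights = TRUE,
                  bounds = c(1e-8, 1e2), tol = 0.001) {
  x <- .fm_values(features,
                  require_stage = if (fold_safe) "scaled" else "residualized")
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 subjects for leave-one-out CV")
  if (length(y) != n) stop("length of y must match the number of subjects")
  if (stats::sd(y) == 0) stop("targets are constant; nothing to predict")
  if (fold_safe && is.null(ages)) stop("fold_safe LOOCV requires ages")

  subject_ids <- if (inherits(features, "feature_matrix"))
    features$subject_ids else rownames(x) %||% as.character(seq_len(n))

  preds <- numeric(n)
  weights <- if (compute_weights) matrix(0, ncol(x), n) else NULL
  sigma2_used <- numeric(n)

  if (!fold_safe && !optimize) {
    k <- compute_gram(x)
    out <- .loocv_gram(k, y, sigma2, keep_alpha = compute_weights)
    preds <- out$predictions
    sigma2_used[] <- sigma2
    if (compute_weights) {
      for (i in seq_len(n)) {
        weights[, i] <- crossprod(x[-i, , drop = FALSE], out$alphas[[i]])
      }
    }
  } else {
    for (i in seq_len(n)) {
      xtr <- x[-i, , drop = FALSE]
      xte <- x[i, , drop = FALSE]
      if (fold_safe) {
        fit_res <- .age_residuals(xtr, ages[-i], return_coef = TRUE)
        xtr <- fit_res$residuals
        xte <- xte - cbind(1, ages[i]) %*% fit_res$coef
      }
      model <- linear_gp(xtr, y[-i], sigma2 = sigma2, optimize = optimize,
                         bounds = bounds, tol = tol)
      preds[i] <- predict(model, xte)
      sigma2_used[i] <- model$sigma2
      if (compute_weights) weights[, i] <- coef(model)
    }
  }

  structure(list(observed = y, predicted = preds, subject_ids = subject_ids,
                 pearson_r = pearson_r(y, preds),
                 fold_weights = weights, sigma2 = sigma2_used,
                 fold_safe = fold_safe),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Leave-one-out CV over %d subjects\n", length(x$observed)))
  cat(sprintf("  Pearson r (observed vs predicted): %.4f\n", x$pearson_r))
  if (x$fold_safe) cat("  (fold-safe age residualization)\n")
  invisible(x)
}

#' Observed-versus-predicted scatter plot
#'
#' @param x A \code{"cv_result"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.cv_result <- function(x, ...) {
  graphics::plot(x$observed, x$predicted,
                 xlab = "Observed", ylab = "Predicted (LOOCV)", ...)
  graphics::abline(stats::lm(x$predicted ~ x$observed), lty = 2)
  graphics::mtext(sprintf("cor = %.3f", x$pearson_r), side = 3, adj = 1)
  invisible(x)
}

## Permutation p-value under the count/B convention: the smallest
## reportable positive p with B permutations is 1/B; a count of zero is
## reported as "p < 1/B".
.perm_pvalue <- function(count, B) {
  p <- count / B
  label <- if (count == 0) sprintf("p < %.3g", 1 / B) else sprintf("p = %.3g", p)
  list(p_value = p, label = label)
}

#' Permutation test of LOOCV prediction accuracy
#'
#' Builds an empirical null by shuffling the target values (breaking the
#' image-score relationship while leaving the images untouched) and
#' re-running the complete leave-one-out cross-validation for each of the
#' \code{B} permutations. The p-value is the fraction of null
#' correlations at least as large as the observed one (one-sided,
#' \code{count / B}); with B = 1000 the smallest reportable positive p is
#' therefore 0.001, and a zero count is reported as \code{p < 1/B}.
#'
#' Each permutation draws its shuffle from a child seed derived from the
#' master \code{seed} by a counter, so enlarging \code{B} never alters
#' earlier draws. The identity permutation is excluded only by chance.
#'
#' @inheritParams loocv
#' @param B Number of permutations (at least 1).
#' @param seed Master seed for the permutation stream.
#' @param alternative \code{"greater"} (the hypothesis is accuracy above
#'   chance) or \code{"two.sided"}.
#' @return An object of class \code{"permutation_result"}: observed
#'   correlation, the B null correlations, \code{p_value}, a display
#'   label, \code{B} and \code{seed}.
#' @export
permutation_test <- function(features, y, B = 1000, seed = 1,
                             sigma2 = 0.001, optimize = FALSE,
                             fold_safe = FALSE, ages = NULL,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (B < 1) stop("B must be at least 1")
  observed <- loocv(features, y, sigma2 = sigma2, optimize = optimize,
                    fold_safe = fold_safe, ages = ages,
                    compute_weights = FALSE)$pearson_r

  ## pre-extract the values matrix once; permutations reuse the Gram
  x <- .fm_values(features,
                  require_stage = if (fold_safe) "scaled" else "residualized")
  fast <- !fold_safe && !optimize
  k <- if (fast) compute_gram(x) else NULL

  null_rs <- numeric(B)
  base_seed <- as.integer(abs(seed) %% 2147000000)
  for (b in seq_len(B)) {
    set.seed(base_seed + b)
    yp <- sample(y)
    if (fast) {
      pr <- .loocv_gram(k, yp, sigma2)$predictions
      null_rs[b] <- stats::cor(yp, pr)
    } else {
      null_rs[b] <- loocv(features, yp, sigma2 = sigma2, optimize = optimize,
                          fold_safe = fold_safe, ages = ages,
                          compute_weights = FALSE)$pearson_r
    }
  }
  count <- if (alternative == "greater") sum(null_rs >= observed)
           else sum(abs(null_rs) >= abs(observed))
  pv <- .perm_pvalue(count, B)
  structure(list(observed_r = observed, null_rs = null_rs,
                 p_value = pv$p_value, p_label = pv$label, B = B,
                 seed = seed, alternative = alternative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations, %s)\n", x$B, x$alternative))
  cat(sprintf("  observed LOOCV r = %.4f, %s\n", x$observed_r, x$p_label))
  invisible(x)
}

#' Null-distribution histogram with the observed statistic marked
#'
#' @param x A \code{"permutation_result"}.
#' @param ... Passed to \code{hist}.
#' @export
plot.permutation_result <- function(x, ...) {
  graphics::hist(x$null_rs, xlab = "Null LOOCV correlation",
                 main = sprintf("Permutation null (B = %d)", x$B),
                 xlim = range(c(x$null_rs, x$observed_r)), ...)
  graphics::abline(v = x$observed_r, col = "red", lwd = 2)
  invisible(x)
}

#' Fold-averaged weight map
#'
#' Averages the per-fold primal weight vectors elementwise and paints the
#' result back onto the (downsampled) brain grid: the multivariate weight
#' map of the most relevant voxels for the prediction, zero outside the
#' mask.
#'
#' @param fold_weights Voxels x folds matrix (from \code{\link{loocv}}),
#'   or a \code{"cv_result"}.
#' @param voxel_index Integer matrix of in-mask voxel coordinates.
#' @param grid_dims Grid dimensions of the analysis resolution.
#' @return A 3-D array of averaged weights.
#' @export
average_weight_map <- function(fold_weights, voxel_index, grid_dims) {
  if (inherits(fold_weights, "cv_result")) {
    if (is.null(fold_weights$fold_weights)) {
      stop("cv_result was computed without fold weights")
    }
    fold_weights <- fold_weights$fold_weights
  }
  fold_weights <- as.matrix(fold_weights)
  if (nrow(fold_weights) != nrow(voxel_index)) {
    stop("weight vector length does not match the voxel index")
  }
  devectorize(rowMeans(fold_weights), voxel_index, grid_dims)
}

#' Cosine similarity between two numeric arrays
#'
#' Used to quantify how well a recovered weight map matches a reference
#' spatial pattern, ignoring overall scale.
#'
#' @param a,b Numeric vectors or arrays of equal length, neither all
#'   zero.
#' @return Cosine of the angle between the flattened arrays.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("inputs must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}
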