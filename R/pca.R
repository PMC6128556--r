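## PCA of the neuropsychological battery: log transform of skewed
## dexterity scores, z-scoring, SVD-based components, variance fractions
## and per-measure contributions.

#' Default 17-measure neuropsychological battery
#'
#' The battery covers intelligence (verbal and performance IQ), planning
#' (Tower of London), finger dexterity (Nine-Hole Peg Test, both hands;
#' log-transformed because completion times are right-skewed), attention
#' (Five Digit Test decoding and inhibiting), visuospatial working memory
#' (Corsi Block-Tapping forward/backward), visuoconstruction and visual
#' memory (Rey-Osterrieth Complex Figure copy/immediate/delayed), verbal
#' fluency (semantic and FAS), verbal working memory (Digit Span
#' forward/backward) and verbal episodic memory (RAVLT immediate recall).
#'
#' @return A data frame with columns \code{measure} and
#'   \code{log_transform}.
#' @export
default_battery <- function() {
  measures <- c("VIQ", "PIQ", "TOL", "NHPT_dom", "NHPT_nondom",
                "FDT_decoding", "FDT_inhibiting", "CBTT_fwd", "CBTT_bwd",
                "ROCF_copy", "ROCF_immediate", "ROCF_delayed",
                "VFT_semantic", "VFT_FAS", "DST_fwd", "DST_bwd",
                "RAVLT_A6")
  data.frame(measure = measures,
             log_transform = measures %in% c("NHPT_dom", "NHPT_nondom"),
             stringsAsFactors = FALSE)
}

#' Read a battery configuration from YAML
#'
#' The file holds a list of entries with fields \code{measure} and
#' optional logical \code{log_transform}, so a custom battery can share
#' all analysis code with the default one.
#'
#' @param path Path to a YAML file.
#' @return A data frame with columns \code{measure}, \code{log_transform}.
#' @export
read_battery <- function(path) {
  raw <- yaml::read_yaml(path)
  data.frame(
    measure = vapply(raw, function(e) as.character(e$measure), character(1)),
    log_transform = vapply(raw, function(e) isTRUE(e$log_transform), logical(1)),
    stringsAsFactors = FALSE)
}

#' Log-transform skewed score columns
#'
#' Replaces the named columns by their base-10 logarithm (used for the
#' right-skewed Nine-Hole Peg Test times). The base is immaterial
#' downstream: after z-scoring, any logarithm base yields the identical
#' standardized column.
#'
#' @param table Data frame of scores.
#' @param columns Character vector of column names to transform.
#' @return The transformed data frame.
#' @export
log_transform <- function(table, columns) {
  for (col in columns) {
    if (!col %in% names(table)) stop(sprintf("column '%s' not found", col))
    v <- table[[col]]
    if (any(v <= 0)) {
      bad <- which(v <= 0)[1]
      stop(sprintf("non-positive value in column '%s', row %d; cannot log-transform",
                   col, bad))
    }
    table[[col]] <- log10(v)
  }
  table
}

#' Centre and scale a score matrix
#'
#' Each column is transformed to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Zero-variance columns are rejected because they
#' carry no information and would produce undefined z-scores.
#'
#' @param x Numeric matrix or data frame of scores.
#' @return A numeric matrix of z-scores.
#' @export
standardize_scores <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0) || any(!is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))[1]
    stop(sprintf("column '%s' has zero variance; cannot standardize",
                 colnames(x)[bad] %||% bad))
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal component analysis of a neuropsychological battery
#'
#' Applies the configured log transforms, z-scores every measure, and
#' extracts principal components by singular value decomposition of the
#' standardized matrix. Components are ordered by decreasing variance;
#' each loading column is sign-flipped so that its largest-magnitude
#' entry is positive, making the decomposition deterministic.
#'
#' Because loading columns have unit norm, the percentage contribution of
#' measure j to component k is \code{100 * loading[j, k]^2}, and each
#' component's contributions sum to 100; the expected average
#' contribution is \code{100 / n_measures}.
#'
#' @param scores Data frame or matrix of raw scores, one row per subject,
#'   one column per measure. A \code{subject_id} column, if present, is
#'   used for labels and excluded from the analysis.
#' @param battery Optional battery configuration (data frame with
#'   \code{measure} and \code{log_transform}); defines column order and
#'   which columns to log-transform.
#' @param log_columns Columns to log-transform when no battery is given.
#' @return An object of class \code{"npsych_pca"} with elements
#'   \code{loadings} (measures x components, orthonormal columns),
#'   \code{scores} (subjects x components), \code{variance_fractions},
#'   \code{contributions} (percentages) and \code{sdev}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(48), 16, 3, dimnames = list(NULL, c("A", "B", "C")))
#' fit <- neuropsych_pca(x)
#' cumulative_variance(fit, 2)
#' @export
neuropsych_pca <- function(scores, battery = NULL, log_columns = character()) {
  scores <- as.data.frame(scores)
  subject_ids <- if ("subject_id" %in% names(scores)) {
    ids <- as.character(scores$subject_id)
    scores$subject_id <- NULL
    ids
  } else rownames(scores) %||% as.character(seq_len(nrow(scores)))
  if (!is.null(battery)) {
    missing_cols <- setdiff(battery$measure, names(scores))
    if (length(missing_cols)) {
      stop("scores are missing battery measures: ",
           paste(missing_cols, collapse = ", "))
    }
    scores <- scores[battery$measure]
    log_columns <- battery$measure[battery$log_transform]
  }
  if (anyNA(scores)) stop("scores contain missing values; exclude incomplete subjects upstream")
  if (nrow(scores) < 2) stop("need at least 2 subjects for PCA")
  scores <- log_transform(scores, log_columns)
  z <- standardize_scores(scores)

  n <- nrow(z); p <- ncol(z)
  k <- min(n - 1, p)
  sv <- svd(z, nu = k, nv = k)
  loadings <- sv$v
  ## deterministic sign: largest-|loading| entry positive in each column
  for (j in seq_len(k)) {
    m <- which.max(abs(loadings[, j]))
    if (loadings[m, j] < 0) loadings[, j] <- -loadings[, j]
  }
  comp_scores <- z %*% loadings
  ev <- sv$d[seq_len(k)]^2 / (n - 1)
  fractions <- ev / sum(sv$d^2 / (n - 1))
  contrib <- 100 * loadings^2
  dimnames(loadings) <- list(colnames(z), paste0("PC", seq_len(k)))
  dimnames(comp_scores) <- list(subject_ids, paste0("PC", seq_len(k)))
  dimnames(contrib) <- dimnames(loadings)

  structure(list(loadings = loadings, scores = comp_scores,
                 variance_fractions = fractions, contributions = contrib,
                 sdev = sqrt(ev), n_measures = p, subject_ids = subject_ids,
                 log_columns = log_columns,
                 standardized = z),
            class = "npsych_pca")
}

#' Per-measure contributions to one principal component
#'
#' @param object An \code{"npsych_pca"} fit.
#' @param k Component index.
#' @return Named numeric vector of percentages summing to 100, with the
#'   expected average contribution (\code{100 / n_measures}) attached as
#'   attribute \code{"expected_average"}.
#' @export
contributions <- function(object, k) {
  stopifnot(inherits(object, "npsych_pca"))
  if (k < 1 || k > ncol(object$loadings)) stop("component index out of range")
  structure(object$contributions[, k],
            expected_average = 100 / object$n_measures)
}

#' Cumulative variance explained by the first k components
#'
#' @param object An \code{"npsych_pca"} fit.
#' @param k Number of leading components.
#' @return Fraction of total variance in (0, 1].
#' @export
cumulative_variance <- function(object, k) {
  stopifnot(inherits(object, "npsych_pca"))
  if (k < 1 || k > length(object$variance_fractions)) {
    stop("component index out of range")
  }
  sum(object$variance_fractions[seq_len(k)])
}

#' @export
print.npsych_pca <- function(x, ...) {
  cat(sprintf("PCA of %d measures, %d subjects\n",
              x$n_measures, nrow(x$scores)))
  vf <- x$variance_fractions
  kshow <- min(5, length(vf))
  cat("  variance explained: ",
      paste(sprintf("PC%d %.1f%%", seq_len(kshow), 100 * vf[seq_len(kshow)]),
            collapse = ", "),
      if (length(vf) > kshow) ", ..." else "", "\n", sep = "")
  cat(sprintf("  first %d components: %.1f%% of variance\n",
              min(3, length(vf)),
              100 * cumulative_variance(x, min(3, length(vf)))))
  invisible(x)
}

#' Scree and contribution plots for a battery PCA
#'
#' @param x An \code{"npsych_pca"} fit.
#' @param which \code{"scree"} for the variance-explained plot or a
#'   component index for its contribution barplot (with the expected
#'   average contribution as a dashed reference line).
#' @param ... Passed to the underlying plotting function.
#' @export
plot.npsych_pca <- function(x, which = "scree", ...) {
  if (identical(which, "scree")) {
    graphics::plot(100 * x$variance_fractions, type = "b",
                   xlab = "Principal component",
                   ylab = "Variance explained (%)", ...)
  } else {
    k <- as.integer(which)
    cb <- contributions(x, k)
    ord <- order(cb, decreasing = TRUE)
    graphics::barplot(cb[ord], las = 2,
                      ylab = sprintf("Contribution to PC%d (%%)", k), ...)
    graphics::abline(h = attr(cb, "expected_average"), lty = 2, col = "red")
  }
  invisible(x)
}
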