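## Group-comparison statistics: pooled two-sample t-tests and Cohen's d
## computed either from raw per-subject data or directly from printed
## summary statistics (means, SDs, group sizes), plus a 2x2 chi-square
## for dichotomous variables such as sex.

#' Summary row for a two-group comparison
#'
#' @param measure Measure label.
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return A validated list of class \code{"summary_row"}.
#' @export
summary_row <- function(measure, m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  structure(list(measure = measure, m1 = m1, s1 = s1, n1 = as.integer(n1),
                 m2 = m2, s2 = s2, n2 = as.integer(n2)),
            class = "summary_row")
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's t-test with pooled variance
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)},
#' \eqn{t = (m_1-m_2)/(s_p\sqrt{1/n_1+1/n_2})}, two-tailed p from the t
#' distribution with \eqn{n_1+n_2-2} degrees of freedom. Computable from
#' a published table's printed means and SDs alone. A Welch variant
#' (unpooled variances, Satterthwaite df) is available via
#' \code{welch = TRUE}.
#'
#' @param row A \code{"summary_row"}.
#' @param welch Use Welch's unequal-variance test instead of the pooled
#'   test.
#' @return A list of class \code{"group_comparison"} with \code{t},
#'   \code{df}, \code{p} (two-tailed) and \code{cohens_d} (pooled-SD
#'   definition regardless of \code{welch}).
#' @export
pooled_t_from_summary <- function(row, welch = FALSE) {
  stopifnot(inherits(row, "summary_row"))
  with(row, {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) stop("zero pooled variance")
    if (welch) {
      se2 <- s1^2 / n1 + s2^2 / n2
      t <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    } else {
      t <- (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    }
    structure(list(measure = measure, t = t, df = df,
                   p = 2 * stats::pt(-abs(t), df),
                   cohens_d = (m1 - m2) / sqrt(sp2)),
              class = "group_comparison")
  })
}

#' Cohen's d with pooled standard deviation
#'
#' \eqn{d = (m_1 - m_2)/s_p}; the sign follows the mean difference.
#'
#' @inheritParams pooled_t_from_summary
#' @return A single numeric value.
#' @export
cohens_d_pooled <- function(row) {
  pooled_t_from_summary(row)$cohens_d
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: t(%g) = %.3f, p = %.3f, d = %.3f\n",
              x$measure, x$df, x$t, x$p, x$cohens_d))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Continuity correction is off by default (matching the usual reporting
#' of \eqn{\chi^2(1)} for group-by-sex tables); enable Yates' correction
#' with \code{correct = TRUE}.
#'
#' @param counts 2x2 matrix of non-negative counts with no zero
#'   marginal.
#' @param correct Apply Yates' continuity correction.
#' @return A list with \code{statistic}, \code{df} (= 1) and \code{p}.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2)) stop("counts must be a 2x2 table")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Whole-table group comparison
#'
#' Runs the pooled t-test and Cohen's d for every measure, either from
#' two raw score tables or from a summary table of printed statistics.
#' The raw-data path applies the configured log transforms, computes each
#' group's mean and SD, and delegates to the summary path, so both
#' routes agree exactly on the same data.
#'
#' @param group1,group2 Data frames of raw scores (columns = measures; a
#'   \code{subject_id} column is ignored). Omit both to use
#'   \code{summary} instead.
#' @param summary Data frame with columns \code{measure, m1, s1, n1, m2,
#'   s2, n2}.
#' @param battery Optional battery configuration restricting and
#'   ordering the measures and naming the log-transformed columns.
#' @param log_columns Columns to log-transform when no battery is given
#'   (raw path only).
#' @param welch Use Welch's test.
#' @return A data frame with one row per measure: group summaries,
#'   \code{t}, \code{df}, \code{p}, \code{d}.
#' @export
compare_groups <- function(group1 = NULL, group2 = NULL, summary = NULL,
                           battery = NULL, log_columns = character(),
                           welch = FALSE) {
  if (!is.null(summary)) {
    rows <- lapply(seq_len(nrow(summary)), function(i) {
      s <- summary[i, ]
      summary_row(s$measure, s$m1, s$s1, s$n1, s$m2, s$s2, s$n2)
    })
  } else {
    if (is.null(group1) || is.null(group2)) {
      stop("provide either two raw tables or a summary table")
    }
    group1 <- as.data.frame(group1)
    group2 <- as.data.frame(group2)
    group1$subject_id <- NULL
    group2$subject_id <- NULL
    if (!is.null(battery)) {
      measures <- battery$measure
      log_columns <- battery$measure[battery$log_transform]
    } else {
      measures <- intersect(names(group1), names(group2))
    }
    miss <- setdiff(measures, intersect(names(group1), names(group2)))
    if (length(miss)) {
      stop("measure mismatch between groups: ", paste(miss, collapse = ", "))
    }
    group1 <- log_transform(group1[measures], log_columns)
    group2 <- log_transform(group2[measures], log_columns)
    rows <- lapply(measures, function(m) {
      summary_row(m, mean(group1[[m]]), stats::sd(group1[[m]]), nrow(group1),
                  mean(group2[[m]]), stats::sd(group2[[m]]), nrow(group2))
    })
  }
  res <- lapply(rows, pooled_t_from_summary, welch = welch)
  data.frame(
    measure = vapply(rows, `[[`, character(1), "measure"),
    m1 = vapply(rows, `[[`, numeric(1), "m1"),
    s1 = vapply(rows, `[[`, numeric(1), "s1"),
    n1 = vapply(rows, `[[`, numeric(1), "n1"),
    m2 = vapply(rows, `[[`, numeric(1), "m2"),
    s2 = vapply(rows, `[[`, numeric(1), "s2"),
    n2 = vapply(rows, `[[`, numeric(1), "n2"),
    t = vapply(res, `[[`, numeric(1), "t"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p = vapply(res, `[[`, numeric(1), "p"),
    d = vapply(res, `[[`, numeric(1), "cohens_d"),
    stringsAsFactors = FALSE)
}
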