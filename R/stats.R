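# Group comparison statistics. The study design compares two arms of
# n = 5 animals on per-animal means; published results report mean ± SD
# per arm, so the two-sample t test must be computable directly from
# summary statistics — that closed form is implemented here.
# Sample-based tests delegate to the standard stats:: implementations.

#' Two-sample t test from summary statistics
#'
#' Unpaired two-tailed t test computed from group means, standard
#' deviations and sizes — the form needed to recompute published
#' comparisons from tabulated mean ± SD values. The pooled variant uses
#' the pooled variance with `n1 + n2 - 2` degrees of freedom; the Welch
#' variant uses per-group variances with Welch–Satterthwaite degrees of
#' freedom. Degenerate input (both SDs zero) yields p = 1 for equal
#' means and p = 0 with a warning otherwise.
#'
#' @param mean1,sd1,n1 first group: mean, SD, size (n >= 2, sd >= 0).
#' @param mean2,sd2,n2 second group.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return Object of class `test_result`: `statistic` (t), `df`
#'   (possibly fractional), `p` (two-tailed), `variant`, `method`.
#' @examples
#' ttest_from_summary(150.2, 12.4, 5, 69.2, 11.9, 5)  # p < 0.001
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2)
      return(test_result(0, n1 + n2 - 2, 1, variant, "two-sample t test (summary)"))
    warning("zero variance in both groups with unequal means; p = 0")
    return(test_result(sign(mean1 - mean2) * Inf, n1 + n2 - 2, 0, variant,
                       "two-sample t test (summary)"))
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(t), df)
  test_result(t, df, p, variant, "two-sample t test (summary)")
}

#' Two-sample t test from samples
#'
#' Computes each group's mean, SD and size and applies
#' [ttest_from_summary()]; by construction it agrees with the summary
#' path to machine precision (and with [stats::t.test()]).
#'
#' @param a,b numeric sample vectors.
#' @param variant `"pooled"` or `"welch"`.
#' @return A `test_result`.
#' @export
ttest_from_samples <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  r <- ttest_from_summary(mean(a), stats::sd(a), length(a),
                          mean(b), stats::sd(b), length(b), variant)
  r$method <- "two-sample t test (samples)"
  r
}

#' Shapiro–Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] returning the package's
#' common result shape; requires 3 to 5000 non-constant observations.
#'
#' @param x numeric sample.
#' @return A `test_result` with `statistic` = W.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("sample is constant")
  s <- stats::shapiro.test(x)
  test_result(unname(s$statistic), NA_real_, s$p.value, NA_character_,
              "Shapiro-Wilk normality test")
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Pearson chi-square without continuity correction (df = 1), via
#' [stats::chisq.test()].
#'
#' @param table 2 x 2 matrix of counts.
#' @return A `test_result` with `statistic` = chi-square.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  s <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result(unname(s$statistic), unname(s$parameter), s$p.value,
              NA_character_, "Pearson chi-square test")
}

#' @keywords internal
test_result <- function(statistic, df, p, variant, method) {
  structure(list(statistic = statistic, df = df, p = p,
                 variant = variant, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %.4g, df = %.4g, p = %s\n",
              x$method,
              if (!is.na(x$variant %||% NA)) paste0(" [", x$variant, "]") else "",
              x$statistic, x$df, format_p(x$p)))
  invisible(x)
}

# p-values formatted the way clinical tables print them (3 decimals,
# "< 0.001" below).
#' @keywords internal
format_p <- function(p) ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))

#' Published per-group summary statistics of the validation study
#'
#' The mean ± SD summary tables of the two study arms (an
#' electromechanical-mapping comparator arm and the MRI-planned arm,
#' n = 5 animals each; arrhythmia counts from the 4 Holter-monitored
#' animals per arm), together with the printed p-values, and the
#' per-arm injection counts. These are inputs for recomputing the group
#' comparisons from summary statistics.
#'
#' @return `study_summaries()`: data frame with one row per tabulated
#'   parameter (`section`, `parameter`, `units`, comparator and planned
#'   `mean`/`sd`/`n`, `printed_p`). `study_injection_counts()`: data
#'   frame with per-arm animal and injection counts.
#' @export
study_summaries <- function() {
  utils::read.csv(system.file("extdata", "study_group_summaries.csv",
                              package = "cartoplan"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname study_summaries
#' @export
study_injection_counts <- function() {
  utils::read.csv(system.file("extdata", "study_injection_counts.csv",
                              package = "cartoplan"),
                  stringsAsFactors = FALSE)
}

#' Recompute the study's group comparisons from summary statistics
#'
#' Applies [ttest_from_summary()] to every row of [study_summaries()],
#' returning the recomputed t, df and p next to the printed p-value.
#' Internally full precision is kept; the `p` column is also given in
#' the 3-decimal table format.
#'
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return Data frame with `t`, `df`, `p` and `p_formatted` appended.
#' @export
recompute_study_tests <- function(variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  df <- study_summaries()
  res <- t(mapply(function(m1, s1, n1, m2, s2, n2) {
    r <- ttest_from_summary(m1, s1, n1, m2, s2, n2, variant)
    c(r$statistic, r$df, r$p)
  }, df$comparator_mean, df$comparator_sd, df$comparator_n,
     df$planned_mean, df$planned_sd, df$planned_n))
  df$t <- res[, 1]; df$df <- res[, 2]; df$p <- res[, 3]
  df$p_formatted <- format_p(df$p)
  df
}
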