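# Univariate screening: normality-gated two-sample comparison, categorical
# tests, and Spearman correlation with the class label.

#' Compare a feature between the two classes
#'
#' Mirrors the classical radiology screening recipe: each group is first
#' checked for normality with a Kolmogorov-Smirnov-type test (Lilliefors
#' correction for estimated mean and sd by default); if both groups pass at
#' `alpha` the two-sided independent-samples t-test is used (equal-variance
#' Student form by default, Welch via `var_equal = FALSE`) and group
#' summaries are reported as mean +- sd, otherwise the two-sided
#' Mann-Whitney U-test is used (exact permutation p for small untied
#' samples, normal approximation with tie and continuity correction
#' otherwise) and summaries are median +- IQR. Groups with zero variance,
#' or too few observations for the normality test (n < 5), are routed to
#' the Mann-Whitney path.
#'
#' @param values Numeric feature values, one per subject.
#' @param labels Binary class labels (0/1, logical, or a two-level factor).
#' @param alpha Significance level for both the normality gate and the
#'   reported `significant` flag.
#' @param feature_name Optional name carried into the result.
#' @param normality `"lilliefors"` (default) or `"ks"` for the plain
#'   Kolmogorov-Smirnov test against the fitted normal.
#' @param test `"auto"` (normality-gated, the default) or a forced path:
#'   `"t"` or `"mann-whitney"`.
#' @param var_equal Use the equal-variance t statistic (default `TRUE`).
#' @param pooled_normality Assess normality on the pooled, group-centered
#'   values instead of per group.
#' @return A one-row tibble: `feature_name`, `test_used`, `p_value`,
#'   `center_0`, `spread_0`, `center_1`, `spread_1`, `summary_type`,
#'   `significant`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 5, 3, 4, 9), c(0, 0, 0, 1, 1, 1))
compare_groups <- function(values, labels, alpha = 0.05, feature_name = NA_character_,
                           normality = c("lilliefors", "ks"),
                           test = c("auto", "t", "mann-whitney"), var_equal = TRUE,
                           pooled_normality = FALSE) {
  normality <- match.arg(normality)
  test <- match.arg(test)
  labels <- as_binary_labels(labels)
  stopifnot(length(values) == length(labels))
  g0 <- values[labels == 0L]
  g1 <- values[labels == 1L]
  if (length(g0) < 2L || length(g1) < 2L) {
    rlang::abort("each group needs at least 2 subjects")
  }

  zero_var <- stats::sd(g0) == 0 || stats::sd(g1) == 0
  normal <- if (test == "t") {
    TRUE
  } else if (test == "mann-whitney" || zero_var) {
    FALSE
  } else if (pooled_normality) {
    group_normal(c(g0 - mean(g0), g1 - mean(g1)), alpha, normality)
  } else {
    group_normal(g0, alpha, normality) && group_normal(g1, alpha, normality)
  }

  if (normal) {
    ht <- stats::t.test(g0, g1, var.equal = var_equal)
    test_used <- "t-test"
    summary_type <- "mean_sd"
    c0 <- mean(g0); s0 <- stats::sd(g0)
    c1 <- mean(g1); s1 <- stats::sd(g1)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(g0, g1))
    test_used <- "mann-whitney"
    summary_type <- "median_iqr"
    c0 <- stats::median(g0); s0 <- stats::IQR(g0)
    c1 <- stats::median(g1); s1 <- stats::IQR(g1)
  }
  tibble::tibble(
    feature_name = feature_name,
    test_used = test_used,
    p_value = ht$p.value,
    center_0 = c0, spread_0 = s0,
    center_1 = c1, spread_1 = s1,
    summary_type = summary_type,
    significant = ht$p.value < alpha
  )
}

group_normal <- function(x, alpha, normality) {
  if (length(unique(x)) < 2L) return(FALSE)
  p <- if (normality == "lilliefors") {
    if (length(x) < 5L) return(FALSE) # too small to assess; be conservative
    nortest::lillie.test(x)$p.value
  } else {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  p > alpha
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1)) || length(u) < 1L) {
    rlang::abort("labels must be binary (0/1)")
  }
  as.integer(labels)
}

#' Univariate screening of a feature table
#'
#' Runs [compare_groups()] and [spearman_with_class()] on every feature
#' column of a wide feature table (all columns except `subject_id` and
#' `class_label` by default). No multiple-testing correction is applied —
#' features are flagged at the nominal per-test level, as is customary in
#' this screening design; interpret the flags accordingly.
#'
#' @param features Wide feature tibble with a `class_label` column.
#' @param alpha Significance level.
#' @param feature_cols Character vector of columns to screen (default: all
#'   non-id columns).
#' @param ... Passed to [compare_groups()].
#' @return A tibble with one row per feature, the [compare_groups()] columns
#'   plus `spearman_r`.
#' @export
univariate_screen <- function(features, alpha = 0.05, feature_cols = NULL, ...) {
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features), c("subject_id", "class_label", "reader"))
  }
  labels <- as_binary_labels(features$class_label)
  purrr::map_dfr(feature_cols, function(fc) {
    res <- compare_groups(features[[fc]], labels, alpha = alpha, feature_name = fc, ...)
    res$spearman_r <- tryCatch(
      spearman_with_class(features[[fc]], labels),
      error = function(e) NA_real_
    )
    res
  })
}

#' Chi-square or Fisher's exact test for a contingency table
#'
#' Follows the usual small-count rule: Fisher's exact test when any
#' expected cell count is below 5 (2 x 2 tables only), Pearson's chi-square
#' without continuity correction otherwise. Larger sparse tables fall back
#' to the chi-square test with a warning.
#'
#' @param table A 2 x k integer matrix of counts (k >= 2).
#' @return A one-row tibble: `test_used`, `p_value`.
#' @export
#' @examples
#' categorical_test(matrix(c(10, 10, 10, 10), 2))
categorical_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L) rlang::abort("expected a 2 x k table, k >= 2")
  if (any(table != round(table)) || any(table < 0)) {
    rlang::abort("contingency counts must be non-negative integers")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    if (ncol(table) == 2L) {
      p <- stats::fisher.test(table)$p.value
      return(tibble::tibble(test_used = "fisher", p_value = p))
    }
    rlang::warn("expected counts < 5 in a 2 x k (k > 2) table; using chi-square anyway")
  }
  p <- suppressWarnings(stats::chisq.test(table, correct = FALSE))$p.value
  tibble::tibble(test_used = "chi-square", p_value = p)
}

#' Spearman correlation of a feature with the class label
#'
#' Rank correlation with midrank ties; the binary class is ranked as 0/1.
#'
#' @param values Numeric feature values.
#' @param labels Binary labels; both classes must be present.
#' @return The correlation coefficient (scalar).
#' @export
spearman_with_class <- function(values, labels) {
  labels <- as_binary_labels(labels)
  if (length(values) < 3L) rlang::abort("need at least 3 subjects")
  if (length(unique(labels)) < 2L) rlang::abort("both classes must be present")
  if (stats::sd(values) == 0) rlang::abort("undefined correlation: constant feature values")
  stats::cor(values, labels, method = "spearman")
}
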