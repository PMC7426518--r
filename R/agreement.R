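# Interobserver agreement: two-way random-effects, absolute-agreement,
# single-measures intraclass correlation — ICC(2,1) — with the customary
# qualitative bands.

#' Intraclass correlation between two readers
#'
#' ICC(2,1): two-way random effects, absolute agreement, single measures,
#' computed from the two-way ANOVA decomposition
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2`
#' raters. Absolute agreement penalizes a systematic shift between readers,
#' so `reader2 = reader1 + c` gives ICC < 1 for `c != 0`. Agreement bands:
#' ICC <= 0.4 poor, <= 0.6 moderate, <= 0.8 good, above excellent.
#'
#' When the measurements have zero total variance the estimator is 0/0; the
#' agreement is trivially perfect and ICC is defined as 1 with
#' `trivial = TRUE`.
#'
#' @param reader1,reader2 Numeric vectors of the same length (>= 3), one
#'   value per subject.
#' @param feature_name Optional name carried into the result.
#' @return A one-row tibble: `feature_name`, `icc`, `band`, `trivial`.
#' @export
#' @examples
#' icc_two_readers(1:10, 1:10 + rnorm(10, sd = 0.1))
icc_two_readers <- function(reader1, reader2, feature_name = NA_character_) {
  if (length(reader1) != length(reader2)) rlang::abort("reader vectors must have equal length")
  n <- length(reader1)
  if (n < 3L) rlang::abort("need at least 3 subjects")
  x <- cbind(reader1, reader2)
  if (any(!is.finite(x))) rlang::abort("non-finite measurements")
  k <- 2L
  grand <- mean(x)
  sst <- sum((x - grand)^2)
  if (sst == 0) {
    return(tibble::tibble(
      feature_name = feature_name, icc = 1, band = "excellent", trivial = TRUE
    ))
  }
  ssb <- k * sum((rowMeans(x) - grand)^2) # between subjects
  ssc <- n * sum((colMeans(x) - grand)^2) # between raters
  sse <- sst - ssb - ssc
  msr <- ssb / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  tibble::tibble(
    feature_name = feature_name,
    icc = icc,
    band = icc_band(icc),
    trivial = FALSE
  )
}

#' Map an ICC value to its qualitative agreement band
#'
#' `<= 0.4` poor, `<= 0.6` moderate, `<= 0.8` good, else excellent.
#'
#' @param icc Numeric vector of ICC values.
#' @return Character vector of bands.
#' @export
icc_band <- function(icc) {
  dplyr::case_when(
    icc <= 0.4 ~ "poor",
    icc <= 0.6 ~ "moderate",
    icc <= 0.8 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Per-feature interobserver agreement table
#'
#' Joins two readers' feature tables on `subject_id` and computes
#' [icc_two_readers()] for every feature column.
#'
#' @param features_r1,features_r2 Wide feature tibbles (one per reader) as
#'   produced by [extract_cohort_features()].
#' @param feature_cols Columns to assess (default: all non-id columns).
#' @return A tibble with one row per feature: `feature_name`, `icc`,
#'   `band`, `trivial`.
#' @export
agreement_table <- function(features_r1, features_r2, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features_r1), c("subject_id", "class_label", "reader"))
  }
  merged <- dplyr::inner_join(
    features_r1[, c("subject_id", feature_cols)],
    features_r2[, c("subject_id", feature_cols)],
    by = "subject_id", suffix = c("_r1", "_r2")
  )
  purrr::map_dfr(feature_cols, function(fc) {
    icc_two_readers(
      merged[[paste0(fc, "_r1")]],
      merged[[paste0(fc, "_r2")]],
      feature_name = fc
    )
  })
}
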