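# Feature assembly: histogram moments plus direction-averaged GLCM/GRLM
# features, and the cohort-level feature table.

#' Histogram (first-order) features of a quantized ROI
#'
#' Skewness and kurtosis of the quantized inside-mask gray levels, using
#' population central moments: `SKE = m3 / m2^(3/2)`,
#' `KUR = m4 / m2^2` (non-excess: a normal distribution gives ~3).
#'
#' @param roi A [normalize_quantize()] result with at least 3 inside-mask
#'   pixels and non-constant levels.
#' @return Named numeric vector `c(SKE, KUR)`.
#' @export
histogram_features <- function(roi) {
  x <- as.numeric(roi$levels[roi$mask])
  if (length(x) < 3L) rlang::abort("histogram features need at least 3 inside-mask pixels")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) rlang::abort("undefined histogram moments: constant ROI levels")
  c(SKE = mean(d^3) / m2^1.5, KUR = mean(d^4) / m2^2)
}

#' All ten texture features of a quantized ROI
#'
#' Computes the two histogram features once and the four GLCM and four GRLM
#' features per direction (0, 45, 90, 135 degrees at distance 1), averaging
#' each second-order feature over the directions in which the matrix is
#' non-empty (a thin mask can have no valid 45- or 135-degree pair; such
#' directions are dropped from the mean rather than zero-filled).
#'
#' On a constant ROI the histogram moments are undefined; `SKE` and `KUR`
#' are returned as `NA` with a warning while the second-order features are
#' still computed.
#'
#' @param roi A [normalize_quantize()] result.
#' @param log_base,inc_variant Passed to [glcm_features()].
#' @return Named numeric vector with elements
#'   `SKE, KUR, CON, ENE, ENT, INC, LRE, RLN, LGLRE, SRLGLE`.
#' @export
#' @examples
#' img <- matrix(runif(256), 16, 16)
#' q <- normalize_quantize(img, matrix(TRUE, 16, 16), n_levels = 8)
#' round(extract_features(q), 3)
extract_features <- function(roi, log_base = 2, inc_variant = "imc1") {
  hist_feats <- tryCatch(
    histogram_features(roi),
    error = function(e) {
      rlang::warn(paste0("histogram features undefined: ", conditionMessage(e)))
      c(SKE = NA_real_, KUR = NA_real_)
    }
  )

  dirs <- names(texture_offsets())
  na_glcm <- c(CON = NA_real_, ENE = NA_real_, ENT = NA_real_, INC = NA_real_)
  na_grlm <- c(LRE = NA_real_, RLN = NA_real_, LGLRE = NA_real_, SRLGLE = NA_real_)
  glcm_mat <- vapply(dirs, function(d) {
    m <- glcm(roi, d)
    if (m$empty) na_glcm else glcm_features(m, log_base = log_base, variant = inc_variant)
  }, numeric(4))
  grlm_mat <- vapply(dirs, function(d) {
    m <- grlm(roi, d)
    if (m$n_runs < 1) na_grlm else grlm_features(m)
  }, numeric(4))

  if (all(is.na(glcm_mat[1, ]))) {
    rlang::abort("no direction has a valid pixel pair: ROI too small for co-occurrence features")
  }
  c(
    hist_feats,
    rowMeans(glcm_mat, na.rm = TRUE),
    rowMeans(grlm_mat, na.rm = TRUE)
  )
}

#' Feature names in canonical order
#' @return Character vector of the ten feature names.
#' @export
texture_feature_names <- function() {
  c("SKE", "KUR", "CON", "ENE", "ENT", "INC", "LRE", "RLN", "LGLRE", "SRLGLE")
}

#' Extract the cohort feature table
#'
#' Quantizes and featurizes every ROI of one reader and returns the wide
#' subjects-by-features table used by the screening and modelling stages:
#' one row per subject, columns `<sequence>_<feature>` (e.g. `sagittal_ENE`,
#' `axial_SRLGLE`) plus `subject_id` and `class_label`.
#'
#' @param samples A cohort tibble from [generate_cohort()] or
#'   [load_manifest()].
#' @param n_levels Gray levels for [normalize_quantize()].
#' @param reader Which reader's masks to use (default 1).
#' @param log_base,inc_variant Passed to [extract_features()].
#' @return A tibble, one row per subject.
#' @export
extract_cohort_features <- function(samples, n_levels = 32L, reader = 1L,
                                    log_base = 2, inc_variant = "imc1") {
  sel <- samples[samples$reader == as.integer(reader), ]
  if (nrow(sel) == 0L) rlang::abort(sprintf("no samples for reader %d", reader))
  long <- sel |>
    dplyr::mutate(
      feats = purrr::map2(.data$image, .data$mask, function(img, msk) {
        q <- normalize_quantize(img, msk, n_levels = n_levels)
        fv <- extract_features(q, log_base = log_base, inc_variant = inc_variant)
        tibble::as_tibble_row(as.list(fv))
      })
    ) |>
    dplyr::select("subject_id", "class_label", "sequence", "feats") |>
    tidyr::unnest("feats") |>
    tidyr::pivot_longer(
      dplyr::all_of(texture_feature_names()),
      names_to = "feature", values_to = "value"
    ) |>
    dplyr::mutate(column = paste(.data$sequence, .data$feature, sep = "_"))
  wide_cols <- as.vector(outer(unique(sel$sequence), texture_feature_names(), paste, sep = "_"))
  long |>
    dplyr::select("subject_id", "class_label", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value") |>
    dplyr::select("subject_id", "class_label", dplyr::all_of(wide_cols))
}
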