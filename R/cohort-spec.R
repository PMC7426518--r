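#' Specify a synthetic two-class ROI cohort
#'
#' A `cohort_spec` describes a simulated study population of tumor regions of
#' interest: two classes (node-negative `0`, node-positive `1`) whose texture
#' heterogeneity is controlled by the correlation length of a smoothed
#' Gaussian random field, two imaging sequences per subject sharing a latent
#' field, and two simulated readers whose masks differ only near the ROI
#' boundary. The positive class is conventionally given the *shorter*
#' correlation length, i.e. the more heterogeneous texture (lower GLCM
#' energy, higher entropy), matching the direction reported for N1-2 tumors.
#'
#' @param n_per_class Subjects per class (>= 2).
#' @param image_size Square image side in pixels (>= 16).
#' @param correlation_length_neg,correlation_length_pos Gaussian smoothing
#'   scale (pixels) of the intensity field for the negative / positive class.
#'   Larger values give smoother, more homogeneous texture.
#' @param noise_sd_neg,noise_sd_pos Standard deviation of i.i.d. pixel noise
#'   added after smoothing, in units of the (unit-variance) smoothed field.
#' @param sequence_coupling Weight in `[0, 1]` of the shared latent field
#'   between the two sequences; `1` makes sagittal and axial identical up to
#'   pixel noise, `0` makes them independent.
#' @param reader_perturb_radius Pixels around the reader-1 mask boundary
#'   within which the reader-2 mask may differ (0 = identical readers).
#' @param seed Master integer seed; every random draw in the cohort is a
#'   pure function of `(seed, subject index, purpose)`.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [cohort_spec_effect()]
#' @export
#' @examples
#' spec <- cohort_spec(n_per_class = 4, image_size = 32, seed = 7)
#' cohort <- generate_cohort(spec)
#' dplyr::count(cohort, class_label, sequence, reader)
cohort_spec <- function(n_per_class = 60,
                        image_size = 64,
                        correlation_length_neg = 3,
                        correlation_length_pos = 3,
                        noise_sd_neg = 0.1,
                        noise_sd_pos = 0.1,
                        sequence_coupling = 0.7,
                        reader_perturb_radius = 2,
                        seed = 1L) {
  spec <- list(
    n_per_class = as.integer(n_per_class),
    image_size = as.integer(image_size),
    correlation_length_neg = as.numeric(correlation_length_neg),
    correlation_length_pos = as.numeric(correlation_length_pos),
    noise_sd_neg = as.numeric(noise_sd_neg),
    noise_sd_pos = as.numeric(noise_sd_pos),
    sequence_coupling = as.numeric(sequence_coupling),
    reader_perturb_radius = as.integer(reader_perturb_radius),
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_per_class < 2L) rlang::abort("n_per_class must be >= 2")
  if (spec$image_size < 16L) rlang::abort("image_size must be >= 16")
  if (spec$correlation_length_neg <= 0 || spec$correlation_length_pos <= 0) {
    rlang::abort("correlation lengths must be > 0")
  }
  if (spec$noise_sd_neg < 0 || spec$noise_sd_pos < 0) {
    rlang::abort("noise standard deviations must be >= 0")
  }
  if (spec$sequence_coupling < 0 || spec$sequence_coupling > 1) {
    rlang::abort("sequence_coupling must be in [0, 1]")
  }
  if (spec$reader_perturb_radius < 0L) {
    rlang::abort("reader_perturb_radius must be >= 0")
  }
  invisible(spec)
}

#' Preset effect sizes for synthetic cohorts
#'
#' Convenience wrapper around [cohort_spec()] fixing the class contrast:
#' `"none"` gives identical texture distributions in both classes (a null
#' cohort for calibration checks), `"small"` a modest separation, `"large"`
#' a strong one (correlation lengths 6 vs 1.5 px).
#'
#' @param effect One of `"none"`, `"small"`, `"large"`.
#' @param ... Passed on to [cohort_spec()] (e.g. `n_per_class`, `seed`).
#' @return A `cohort_spec`.
#' @export
cohort_spec_effect <- function(effect = c("none", "small", "large"), ...) {
  effect <- match.arg(effect)
  cl <- switch(effect,
    none  = c(3, 3),
    small = c(3.5, 2.5),
    large = c(6, 1.5)
  )
  cohort_spec(correlation_length_neg = cl[1], correlation_length_pos = cl[2], ...)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d subjects/class, %dx%d px\n", x$n_per_class, x$image_size, x$image_size))
  cat(sprintf(
    "  correlation length neg/pos: %.2f / %.2f px; noise sd: %.3f / %.3f\n",
    x$correlation_length_neg, x$correlation_length_pos,
    x$noise_sd_neg, x$noise_sd_pos
  ))
  cat(sprintf(
    "  sequence coupling %.2f, reader perturbation %d px, seed %d\n",
    x$sequence_coupling, x$reader_perturb_radius, x$seed
  ))
  invisible(x)
}
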