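# Synthetic cohort generation: Gaussian-random-field textures, blob masks,
# and boundary-perturbed second-reader masks.

# purpose tags for sub-seed derivation
.PURPOSE <- c(
  latent = 1L, noise_sag = 2L, noise_ax = 3L,
  pixel_sag = 4L, pixel_ax = 5L, mask = 6L, reader = 7L
)

#' Generate a synthetic two-class ROI cohort
#'
#' Draws, for every subject, a smoothed Gaussian random field whose
#' correlation length depends on the class (shorter length = more
#' heterogeneous texture, standing in for the higher tumor heterogeneity of
#' node-positive disease), mixes a shared latent field into the two imaging
#' sequences, adds pixel noise, and rescales each image to positive 16-bit
#' integers. The ROI mask is an irregular central blob obtained by
#' thresholding a separately smoothed field; the second reader's mask is
#' derived from the first by random inclusion/exclusion of pixels within
#' `reader_perturb_radius` of the boundary.
#'
#' The output is fully deterministic in the spec (including its seed), and
#' every subject's draws depend only on `(seed, subject index, purpose)`, so
#' enlarging the cohort never changes earlier subjects.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per (subject, sequence, reader):
#'   `subject_id`, `class_label` (0/1), `sequence` (`"sagittal"`/`"axial"`),
#'   `reader` (1/2), and list-columns `image` (integer matrix) and `mask`
#'   (logical matrix).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_class = 2, image_size = 32))
#' cohort
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n_total <- 2L * spec$n_per_class
  rows <- purrr::map(seq_len(n_total), function(s) {
    class_label <- if (s <= spec$n_per_class) 0L else 1L
    subj <- generate_subject(spec, s, class_label)
    tidyr::expand_grid(
      sequence = c("sagittal", "axial"),
      reader = c(1L, 2L)
    ) |>
      dplyr::mutate(
        subject_id = subj$subject_id,
        class_label = class_label,
        image = purrr::map(.data$sequence, function(sq) subj$images[[sq]]),
        mask = purrr::map2(.data$sequence, .data$reader, function(sq, rd) {
          subj$masks[[paste0(sq, "_r", rd)]]
        })
      )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("subject_id", "class_label", "sequence", "reader", "image", "mask")
  class(out) <- c("roi_cohort", class(out))
  out
}

generate_subject <- function(spec, s, class_label) {
  S <- spec$image_size
  cl <- if (class_label == 1L) spec$correlation_length_pos else spec$correlation_length_neg
  nsd <- if (class_label == 1L) spec$noise_sd_pos else spec$noise_sd_neg
  w <- spec$sequence_coupling

  latent <- with_subseed(subseed(spec$seed, s, .PURPOSE[["latent"]]), {
    standardize(smooth_field(matrix(stats::rnorm(S * S), S, S), cl))
  })

  make_image <- function(noise_tag, pixel_tag) {
    own <- with_subseed(subseed(spec$seed, s, noise_tag), {
      standardize(smooth_field(matrix(stats::rnorm(S * S), S, S), cl))
    })
    field <- sqrt(w) * latent + sqrt(1 - w) * own
    if (nsd > 0) {
      field <- field + with_subseed(
        subseed(spec$seed, s, pixel_tag),
        matrix(stats::rnorm(S * S, sd = nsd), S, S)
      )
    }
    rescale_to_uint16(field)
  }

  images <- list(
    sagittal = make_image(.PURPOSE[["noise_sag"]], .PURPOSE[["pixel_sag"]]),
    axial = make_image(.PURPOSE[["noise_ax"]], .PURPOSE[["pixel_ax"]])
  )

  masks <- generate_masks(spec, s)

  list(
    subject_id = sprintf("S%03d", s),
    class_label = class_label,
    images = images,
    masks = list(
      sagittal_r1 = masks$r1, sagittal_r2 = masks$r2,
      axial_r1 = masks$r1, axial_r2 = masks$r2
    )
  )
}

standardize <- function(m) {
  s <- stats::sd(as.vector(m))
  if (s == 0) return(m * 0)
  (m - mean(m)) / s
}

rescale_to_uint16 <- function(field, lo = 200L, hi = 60000L) {
  rng <- range(field)
  if (rng[1] == rng[2]) {
    return(matrix(as.integer((lo + hi) %/% 2L), nrow(field), ncol(field)))
  }
  m <- round((field - rng[1]) / (rng[2] - rng[1]) * (hi - lo)) + lo
  matrix(as.integer(m), nrow(field), ncol(field))
}

# Blob mask: threshold of a smoothed field plus a central bump; largest
# 4-connected component, >= 64 px. Degenerate draws are retried with a
# derived sub-seed (up to 100 attempts).
generate_masks <- function(spec, s) {
  S <- spec$image_size
  r <- spec$reader_perturb_radius
  keep_frac <- min(0.5, max(0.15, 96 / (S * S)))
  ctr <- (S + 1) / 2
  d2 <- outer(seq_len(S) - ctr, seq_len(S) - ctr, function(a, b) a^2 + b^2)
  bump <- 2 * exp(-d2 / (2 * (S / 5)^2))

  for (attempt in seq_len(100L)) {
    tag <- .PURPOSE[["mask"]] + 100L * (attempt - 1L)
    field <- with_subseed(subseed(spec$seed, s, tag), {
      standardize(smooth_field(matrix(stats::rnorm(S * S), S, S), S / 8))
    }) + bump
    thr <- stats::quantile(field, 1 - keep_frac)
    mask <- largest_component(field > thr)
    if (sum(mask) < 64L) next
    if (r == 0L) return(list(r1 = mask, r2 = mask))

    core <- erode4(mask, r)
    if (!any(core)) next
    band <- dilate4(mask, r) & !core
    # readers agree over most of the boundary: a band pixel flips only where
    # a smooth standardized perturbation field exceeds +-1 sd (~16% of the
    # band in each direction), emulating locally coherent over/under-drawing
    perturb <- with_subseed(subseed(spec$seed, s, tag + 1L), {
      standardize(smooth_field(matrix(stats::rnorm(S * S), S, S), 2))
    })
    r2 <- (mask & !(band & mask & perturb < -1)) | (band & !mask & perturb > 1)
    # keep only the component attached to the core; stray band fragments may
    # be dropped (still within the perturbation band), but if the core itself
    # ends up split across components the draw is retried so that reader 2
    # never loses interior pixels
    lab <- label4(r2)
    core_labs <- unique(lab[core])
    if (length(core_labs) != 1L) next
    r2 <- lab == core_labs
    if (sum(r2) >= 64L) return(list(r1 = mask, r2 = r2))
  }
  rlang::abort(sprintf(
    "failed to generate a valid ROI mask for subject %d after 100 attempts (image_size %d may be too small)",
    s, S
  ))
}
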