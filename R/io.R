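# Cohort I/O: PNG/NIfTI readers, manifest + labels loading, feature-table
# round trips, and the cohort writer.

#' Write a cohort to disk
#'
#' Writes one 16-bit grayscale PNG per (subject, sequence) image and one
#' 8-bit binary PNG per (subject, sequence, reader) mask, plus
#' `labels.csv` (`subject_id`, `class_label`) and `manifest.csv`
#' (`subject_id`, `sequence`, `reader`, `image_path`, `mask_path`; paths
#' relative to the manifest). The written files round-trip losslessly
#' through [load_manifest()].
#'
#' @param cohort A cohort tibble from [generate_cohort()] or
#'   [load_manifest()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)

  imgs <- dplyr::distinct(cohort, .data$subject_id, .data$sequence, .keep_all = TRUE)
  for (i in seq_len(nrow(imgs))) {
    p <- file.path(out_dir, "images", sprintf("%s_%s.png", imgs$subject_id[i], imgs$sequence[i]))
    ok <- tryCatch(write_png16(imgs$image[[i]], p), error = function(e) NULL)
    if (is.null(ok)) rlang::abort(paste0("failed to write image: ", p))
  }
  manifest <- cohort |>
    dplyr::mutate(
      image_path = file.path("images", sprintf("%s_%s.png", .data$subject_id, .data$sequence)),
      mask_path = file.path("masks", sprintf("%s_%s_r%d.png", .data$subject_id, .data$sequence, .data$reader))
    )
  for (i in seq_len(nrow(manifest))) {
    p <- file.path(out_dir, manifest$mask_path[i])
    ok <- tryCatch(
      png::writePNG(matrix(as.numeric(manifest$mask[[i]]), nrow(manifest$mask[[i]])), p),
      error = function(e) NULL
    )
    if (is.null(ok) && !file.exists(p)) rlang::abort(paste0("failed to write mask: ", p))
  }
  labels <- dplyr::distinct(cohort, .data$subject_id, .data$class_label)
  readr::write_csv(labels, file.path(out_dir, "labels.csv"))
  manifest_path <- file.path(out_dir, "manifest.csv")
  manifest |>
    dplyr::select("subject_id", "sequence", "reader", "image_path", "mask_path") |>
    readr::write_csv(manifest_path)
  invisible(manifest_path)
}

#' Load a cohort from a manifest
#'
#' Reads every row of a manifest CSV (`subject_id`, `sequence`, `reader`,
#' `image_path`, `mask_path`; paths relative to the manifest directory or
#' absolute) into the cohort tibble used throughout the package. PNG (8- or
#' 16-bit grayscale) and single-slice NIfTI (`.nii` / `.nii.gz`, a singleton
#' third axis is squeezed) are accepted for both images and masks. An
#' optional labels CSV (`subject_id`, `class_label`) attaches the binary
#' class; subjects without a label get `NA`.
#'
#' Validation: image and mask of a row must have identical shape, the mask
#' at least one inside pixel, intensities must be finite and non-negative,
#' `sequence` must be `sagittal` or `axial`, `reader` 1 or 2, and
#' (subject, sequence, reader) must be unique.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param labels_path Optional path to the labels CSV.
#' @return A cohort tibble (see [generate_cohort()] for the schema).
#' @export
load_manifest <- function(manifest_path, labels_path = NULL) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  need <- c("subject_id", "sequence", "reader", "image_path", "mask_path")
  if (!all(need %in% names(manifest))) {
    rlang::abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")))
  }
  bad_seq <- setdiff(unique(manifest$sequence), c("sagittal", "axial"))
  if (length(bad_seq) > 0) {
    rlang::abort(paste0("unknown sequence value(s): ", paste(bad_seq, collapse = ", ")))
  }
  if (!all(manifest$reader %in% c(1L, 2L))) rlang::abort("reader must be 1 or 2")
  dup <- manifest |>
    dplyr::count(.data$subject_id, .data$sequence, .data$reader) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    rlang::abort(sprintf(
      "duplicate (subject, sequence, reader) in manifest: %s/%s/r%d",
      dup$subject_id[1], dup$sequence[1], dup$reader[1]
    ))
  }

  base_dir <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))

  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- readr::read_csv(labels_path, show_col_types = FALSE)
    if (!all(c("subject_id", "class_label") %in% names(labels))) {
      rlang::abort("labels CSV must have columns subject_id, class_label")
    }
  }

  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    where <- sprintf("subject %s, sequence %s, reader %d (manifest row %d)",
                     row$subject_id, row$sequence, row$reader, i)
    img_p <- resolve(row$image_path)
    msk_p <- resolve(row$mask_path)
    for (p in c(img_p, msk_p)) {
      if (!file.exists(p)) rlang::abort(paste0("missing file for ", where, ": ", p))
    }
    img <- read_roi_image(img_p)
    msk <- read_roi_image(msk_p) > 0.5
    if (!all(dim(img) == dim(msk))) {
      rlang::abort(paste0("image/mask shape mismatch for ", where))
    }
    if (!any(msk)) rlang::abort(paste0("empty ROI mask for ", where))
    if (any(!is.finite(img)) || any(img < 0)) {
      rlang::abort(paste0("intensities must be finite and >= 0 for ", where))
    }
    tibble::tibble(
      subject_id = row$subject_id,
      sequence = row$sequence,
      reader = as.integer(row$reader),
      image = list(img),
      mask = list(msk)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(labels)) {
    out <- dplyr::left_join(out, labels[, c("subject_id", "class_label")], by = "subject_id")
  } else {
    out$class_label <- NA_integer_
  }
  out <- dplyr::select(out, "subject_id", "class_label", "sequence", "reader", "image", "mask")
  class(out) <- c("roi_cohort", class(out))
  out
}

# Read a 2D grayscale image: PNG (values rescaled back to the integer range
# of the file's bit depth) or NIfTI (singleton third axis squeezed).
read_roi_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path, info = TRUE)
    depth <- attr(a, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    if (length(dim(a)) == 3L) {
      ch <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
      same <- all(vapply(ch[-1], function(m) identical(m, ch[[1]]), logical(1)))
      if (!same) rlang::abort(paste0("not a grayscale image: ", path))
      a <- ch[[1]]
    }
    return(matrix(round(a * (2^depth - 1)), nrow(a), ncol(a)))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    a <- RNifti::readNifti(path)
    d <- dim(a)
    if (length(d) > 2L) {
      if (all(d[-(1:2)] == 1L)) {
        a <- array(a, dim = d[1:2])
      } else {
        rlang::abort(paste0("NIfTI image is not a single slice: ", path))
      }
    }
    return(matrix(as.numeric(a), dim(a)[1], dim(a)[2]))
  }
  rlang::abort(paste0("unsupported image format (expect .png, .nii, .nii.gz): ", path))
}

#' Write / read a feature table
#'
#' CSV round trip of the subjects-by-features table produced by
#' [extract_cohort_features()]. Numbers are written in shortest
#' round-trippable form, so read-back equals the original to full double
#' precision.
#'
#' @param table Feature tibble.
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the tibble.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
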