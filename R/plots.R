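#' Display an ROI sample
#'
#' Renders one cohort row's image as a grayscale raster with the mask
#' outlined in red (mask boundary = inside pixels with at least one
#' 4-neighbor outside).
#'
#' @param cohort A cohort tibble.
#' @param subject,sequence,reader Row selector; defaults to the first row.
#' @return A ggplot object.
#' @export
plot_roi <- function(cohort, subject = NULL, sequence = "sagittal", reader = 1L) {
  if (is.null(subject)) subject <- cohort$subject_id[1]
  i <- which(cohort$subject_id == subject &
               cohort$sequence == sequence & cohort$reader == reader)
  if (length(i) == 0L) rlang::abort("no matching cohort row")
  img <- cohort$image[[i[1]]]
  msk <- cohort$mask[[i[1]]]
  edge <- msk & !erode4(msk, 1L)
  d <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  d$intensity <- as.vector(t(img)) # expand_grid varies col fastest = row-major
  d$edge <- as.vector(t(edge))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(
      data = d[d$edge, ], color = "red", size = 0.3
    ) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s / %s / reader %d", subject, sequence, reader),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_void()
}

#' Volcano-style view of the univariate screen
#'
#' Plots each feature's Spearman correlation with the class against
#' `-log10(p)`, with the significance level marked.
#'
#' @param univariate A [univariate_screen()] result.
#' @param alpha Significance level line.
#' @return A ggplot object.
#' @export
plot_univariate <- function(univariate, alpha = 0.05) {
  ggplot2::ggplot(
    univariate,
    ggplot2::aes(x = .data$spearman_r, y = -log10(.data$p_value),
                 color = .data$significant)
  ) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(
      data = univariate[univariate$significant, ],
      ggplot2::aes(label = .data$feature_name),
      size = 2.5, vjust = -0.8, show.legend = FALSE
    ) +
    ggplot2::labs(x = "Spearman correlation with class",
                  y = expression(-log[10](p)), color = "significant") +
    ggplot2::theme_minimal()
}
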