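# ROC evaluation: empirical AUC with DeLong confidence interval (via pROC)
# and the Youden-optimal operating point with its Table-style cutoff rule.

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical ROC over all observed thresholds. The AUC is the Mann-Whitney
#' concordance probability (ties count 1/2) with a 95% DeLong confidence
#' interval; the score direction is chosen so that AUC >= 0.5 and is
#' reported as a cutoff rule (`"> c"` when higher scores indicate the
#' positive class, `"< c"` otherwise). The operating cutoff maximizes the
#' Youden index J = sensitivity + specificity - 1; ties in J are broken
#' toward higher sensitivity. Sensitivity, specificity and accuracy
#' (correctly classified fraction at the cutoff) are reported in percent.
#'
#' Constant scores give a degenerate ROC: AUC 0.5, no cutoff, and
#' `degenerate = TRUE`.
#'
#' @param scores Numeric scores (feature values or fitted probabilities).
#' @param labels Binary class labels (1 = positive).
#' @param conf_level Confidence level for the DeLong interval.
#' @return An object of class `roc_summary`: list with `auc`, `auc_low`,
#'   `auc_high`, `youden_cutoff`, `cutoff_rule`, `sensitivity`,
#'   `specificity`, `accuracy` (percentages), `direction` (`">"` or `"<"`),
#'   `n_pos`, `n_neg`, `degenerate`, and `curve` (tibble with `threshold`,
#'   `sensitivity`, `specificity`).
#' @seealso [tidy.roc_summary()], [glance.roc_summary()],
#'   [autoplot.roc_summary()]
#' @export
#' @examples
#' roc_analysis(c(0.9, 0.8, 0.2, 0.3), c(1, 1, 0, 0))
roc_analysis <- function(scores, labels, conf_level = 0.95) {
  y <- as_binary_labels(labels)
  s <- as.numeric(scores)
  if (length(s) != length(y)) rlang::abort("scores and labels must have equal length")
  if (length(unique(y)) < 2L) rlang::abort("both classes must be present")
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)

  if (stats::sd(s) == 0) {
    rlang::warn("constant scores: ROC is degenerate (AUC 0.5, no cutoff)")
    out <- list(
      auc = 0.5, auc_low = NA_real_, auc_high = NA_real_,
      youden_cutoff = NA_real_, cutoff_rule = NA_character_,
      sensitivity = NA_real_, specificity = NA_real_, accuracy = NA_real_,
      direction = NA_character_, n_pos = n_pos, n_neg = n_neg,
      degenerate = TRUE,
      curve = tibble::tibble(
        threshold = numeric(), sensitivity = numeric(), specificity = numeric()
      )
    )
    class(out) <- "roc_summary"
    return(out)
  }

  # direction chosen so that AUC >= 0.5 (pROC's "auto" compares medians,
  # which can disagree with the AUC criterion on skewed score distributions)
  r <- pROC::roc(response = y, predictor = s, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  if (as.numeric(pROC::auc(r)) < 0.5) {
    r <- pROC::roc(response = y, predictor = s, levels = c(0, 1),
                   direction = ">", quiet = TRUE)
  }
  auc <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong")))

  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[is.finite(co$threshold), , drop = FALSE]
  j <- co$sensitivity + co$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.max(co$sensitivity[best])]
  cutoff <- co$threshold[best]

  # pROC direction "<" means controls < cases: higher score = positive class
  higher_is_positive <- r$direction == "<"
  pred_pos <- if (higher_is_positive) s > cutoff else s < cutoff
  accuracy <- mean(pred_pos == (y == 1L)) * 100

  out <- list(
    auc = auc,
    auc_low = ci[1], auc_high = ci[3],
    youden_cutoff = cutoff,
    cutoff_rule = sprintf("%s %.4g", if (higher_is_positive) ">" else "<", cutoff),
    sensitivity = co$sensitivity[best] * 100,
    specificity = co$specificity[best] * 100,
    accuracy = accuracy,
    direction = if (higher_is_positive) ">" else "<",
    n_pos = n_pos, n_neg = n_neg,
    degenerate = FALSE,
    curve = tibble::tibble(
      threshold = co$threshold,
      sensitivity = co$sensitivity,
      specificity = co$specificity
    )
  )
  class(out) <- "roc_summary"
  out
}

#' @export
print.roc_summary <- function(x, ...) {
  if (x$degenerate) {
    cat("<roc_summary> degenerate (constant scores), AUC 0.5\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<roc_summary> AUC %.3f (95%% CI %.3f-%.3f), cutoff %s\n",
    x$auc, x$auc_low, x$auc_high, x$cutoff_rule
  ))
  cat(sprintf(
    "  sensitivity %.2f%%, specificity %.2f%%, accuracy %.2f%% (%d pos / %d neg)\n",
    x$sensitivity, x$specificity, x$accuracy, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Tidy the ROC curve points
#' @param x A [roc_analysis()] result.
#' @param ... Unused.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`.
#' @export
tidy.roc_summary <- function(x, ...) x$curve

#' One-row ROC summary
#' @param x A [roc_analysis()] result.
#' @param ... Unused.
#' @return One-row tibble with the AUC, CI, cutoff and operating metrics.
#' @export
glance.roc_summary <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_low = x$auc_low, auc_high = x$auc_high,
    youden_cutoff = x$youden_cutoff, cutoff_rule = x$cutoff_rule,
    sensitivity = x$sensitivity, specificity = x$specificity,
    accuracy = x$accuracy, n_pos = x$n_pos, n_neg = x$n_neg,
    degenerate = x$degenerate
  )
}

#' Plot a ROC curve
#' @param object A [roc_analysis()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_summary <- function(object, ...) {
  if (object$degenerate) rlang::abort("cannot plot a degenerate ROC")
  d <- object$curve |>
    dplyr::arrange(dplyr::desc(.data$specificity), .data$sensitivity)
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)", object$auc, object$auc_low, object$auc_high)
    ) +
    ggplot2::theme_minimal()
}
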