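# Scope-wise modelling: for each feature scope (sagittal-only, axial-only,
# combined) take the univariately significant features as candidates, run
# forward-stepwise logistic regression, and evaluate the fitted
# probabilities by ROC at the Youden cutoff (in-sample, as in the classical
# single-cohort design).

#' Run the stepwise-model suite over feature scopes
#'
#' For each requested scope, the candidate set is the univariately
#' significant features whose column name starts with that sequence prefix
#' (`combined` = union of both). Scopes without significant candidates are
#' skipped with a warning. Evaluation is in-sample: the ROC is computed on
#' the fitted probabilities of the same subjects the model was fit on, so
#' reported AUCs are optimistic relative to external validation.
#'
#' @param features Wide feature tibble with `class_label`.
#' @param univariate Result of [univariate_screen()] on (a superset of) the
#'   feature columns.
#' @param scopes Subset of `c("sagittal", "axial", "combined")`.
#' @param entry_p,removal_p Stepwise thresholds.
#' @return A tibble of class `model_suite`, one row per fitted scope:
#'   `scope`, `candidates` (list), `model` (list of `stepwise_logit`),
#'   `roc` (list of `roc_summary`).
#' @export
run_model_suite <- function(features, univariate,
                            scopes = c("sagittal", "axial", "combined"),
                            entry_p = 0.05, removal_p = 0.10) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  sig <- univariate$feature_name[univariate$significant]
  labels <- as_binary_labels(features$class_label)

  rows <- purrr::map(scopes, function(sc) {
    cand <- if (sc == "combined") {
      sig
    } else {
      sig[startsWith(sig, paste0(sc, "_"))]
    }
    if (length(cand) == 0L) {
      rlang::warn(sprintf("scope '%s': no univariately significant candidate; skipped", sc))
      return(NULL)
    }
    model <- forward_stepwise_logistic(
      features, outcome = "class_label", candidates = cand,
      entry_p = entry_p, removal_p = removal_p
    )
    roc <- if (length(model$selected) > 0L) {
      roc_analysis(stats::fitted(model$fit), labels)
    } else {
      rlang::warn(sprintf("scope '%s': stepwise selected no feature; ROC skipped", sc))
      NULL
    }
    tibble::tibble(
      scope = sc,
      candidates = list(cand),
      model = list(model),
      roc = list(roc)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("model_suite", class(out))
  out
}

#' Tidy a model suite
#'
#' One row per (scope, selected feature) with odds ratios and Wald
#' confidence intervals, plus the scope-level ROC summary columns.
#'
#' @param x A [run_model_suite()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.model_suite <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    td <- tidy(x$model[[i]])
    if (nrow(td) == 0L) return(NULL)
    td$scope <- x$scope[i]
    roc <- x$roc[[i]]
    if (!is.null(roc)) {
      td$auc <- roc$auc
      td$cutoff_rule <- roc$cutoff_rule
    }
    dplyr::select(td, "scope", dplyr::everything())
  })
}

#' Scope-level summary of a model suite
#'
#' @param x A [run_model_suite()] result.
#' @param ... Unused.
#' @return One row per scope: selection count, Hosmer-Lemeshow p, AUC with
#'   CI, Youden cutoff and operating metrics.
#' @export
glance.model_suite <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    g <- glance(x$model[[i]])
    roc <- x$roc[[i]]
    r <- if (is.null(roc)) {
      tibble::tibble(
        auc = NA_real_, auc_low = NA_real_, auc_high = NA_real_,
        youden_cutoff = NA_real_, cutoff_rule = NA_character_,
        sensitivity = NA_real_, specificity = NA_real_, accuracy = NA_real_
      )
    } else {
      glance(roc)[, c("auc", "auc_low", "auc_high", "youden_cutoff",
                      "cutoff_rule", "sensitivity", "specificity", "accuracy")]
    }
    dplyr::bind_cols(tibble::tibble(scope = x$scope[i]), g, r)
  })
}
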