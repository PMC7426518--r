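# Forward-stepwise logistic regression with likelihood-ratio entry and
# removal tests (the "Forward: LR" convention of classical stats suites):
# at each step the candidate with the smallest LR p-value enters if it is
# below entry_p; after every entry, included variables whose LR removal
# p-value exceeds removal_p are dropped; iterate to a fixed point.

#' Forward-stepwise logistic regression
#'
#' Binary-outcome logistic regression with forward selection by
#' likelihood-ratio test (entry when the best candidate's LR p-value is
#' below `entry_p`) and backward elimination after each entry (removal when
#' an included variable's LR p-value exceeds `removal_p`). The final model
#' is fit by maximum likelihood via iteratively reweighted least squares
#' (Newton's method for the canonical logit link) to convergence.
#'
#' Perfect or quasi-perfect separation is flagged per feature (diverging
#' coefficient or fitted probabilities numerically 0/1).
#'
#' @param data Data frame holding the outcome and candidate columns.
#' @param outcome Name of the binary outcome column (0/1).
#' @param candidates Character vector of candidate feature columns.
#' @param entry_p Entry threshold (default 0.05).
#' @param removal_p Removal threshold (default 0.10).
#' @param max_steps Safety bound on selection iterations.
#' @return An object of class `stepwise_logit`: list with `fit` (the final
#'   `glm`), `selected` (ordered character vector), `steps` (tibble of
#'   entry/removal actions with their LR p-values), `entry_p`, `removal_p`,
#'   `separation` (named logical), `hl` (Hosmer-Lemeshow tibble for the
#'   final model, `NULL` for an empty model), and `n`.
#' @seealso [tidy.stepwise_logit()], [glance.stepwise_logit()],
#'   [hosmer_lemeshow()]
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(y = rep(0:1, each = 30))
#' d$signal <- d$y + rnorm(60, sd = 0.6)
#' d$noise <- rnorm(60)
#' fit <- forward_stepwise_logistic(d, "y", c("signal", "noise"))
#' fit$selected
forward_stepwise_logistic <- function(data, outcome, candidates,
                                      entry_p = 0.05, removal_p = 0.10,
                                      max_steps = 50L) {
  y <- as_binary_labels(data[[outcome]])
  if (anyNA(data[, c(outcome, candidates)])) rlang::abort("missing values in outcome or candidates")
  if (min(table(y)) < 10L) {
    rlang::warn("fewer than 10 subjects in a class; stepwise selection may be unstable")
  }
  df <- data
  df[[outcome]] <- y

  fit_model <- function(vars) {
    fml <- if (length(vars) == 0L) {
      stats::as.formula(paste(outcome, "~ 1"))
    } else {
      stats::as.formula(paste(outcome, "~", paste(sprintf("`%s`", vars), collapse = " + ")))
    }
    suppressWarnings(stats::glm(
      fml, family = stats::binomial(), data = df,
      control = stats::glm.control(epsilon = 1e-10, maxit = 100L)
    ))
  }
  lr_p <- function(small, big) {
    stats::pchisq(small$deviance - big$deviance, df = 1L, lower.tail = FALSE)
  }

  selected <- character(0)
  current_fit <- fit_model(selected)
  steps <- list()
  for (step_i in seq_len(max_steps)) {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0L) {
      entry <- purrr::map_dbl(pool, function(v) lr_p(current_fit, fit_model(c(selected, v))))
      best <- which.min(entry)
      if (entry[best] < entry_p) {
        selected <- c(selected, pool[best])
        current_fit <- fit_model(selected)
        steps[[length(steps) + 1L]] <- tibble::tibble(
          step = step_i, action = "enter", feature = pool[best], p_value = entry[best]
        )
        changed <- TRUE
      }
    }
    repeat {
      if (length(selected) == 0L) break
      removal <- purrr::map_dbl(selected, function(v) {
        lr_p(fit_model(setdiff(selected, v)), current_fit)
      })
      worst <- which.max(removal)
      if (removal[worst] > removal_p) {
        steps[[length(steps) + 1L]] <- tibble::tibble(
          step = step_i, action = "remove", feature = selected[worst],
          p_value = removal[worst]
        )
        selected <- setdiff(selected, selected[worst])
        current_fit <- fit_model(selected)
        changed <- TRUE
      } else {
        break
      }
    }
    if (!changed) break
  }

  if (!current_fit$converged) {
    rlang::abort(sprintf(
      "logistic fit did not converge in %d IRLS iterations (selected: %s)",
      current_fit$control$maxit, paste(selected, collapse = ", ")
    ))
  }
  cf <- stats::coef(current_fit)[-1]
  fitted_p <- stats::fitted(current_fit)
  separation <- if (length(cf) > 0) {
    abs(cf) > 15 | any(fitted_p < 1e-8 | fitted_p > 1 - 1e-8)
  } else {
    logical(0)
  }
  names(separation) <- names(cf)
  if (any(separation)) {
    rlang::warn(paste0(
      "possible separation for: ",
      paste(names(separation)[separation], collapse = ", ")
    ))
  }

  hl <- if (length(selected) > 0L && length(y) >= 20L) {
    hosmer_lemeshow(fitted_p, y)
  } else {
    NULL
  }

  structure(
    list(
      fit = current_fit,
      selected = selected,
      steps = if (length(steps) > 0) dplyr::bind_rows(steps) else
        tibble::tibble(step = integer(), action = character(),
                       feature = character(), p_value = numeric()),
      entry_p = entry_p,
      removal_p = removal_p,
      separation = separation,
      hl = hl,
      n = length(y)
    ),
    class = "stepwise_logit"
  )
}

#' Tidy a stepwise logistic model
#'
#' One row per selected feature: coefficient, Wald standard error and
#' p-value, odds ratio `exp(coefficient)` with its 95% Wald confidence
#' interval `exp(coefficient +- 1.96 se)`.
#'
#' @param x A [forward_stepwise_logistic()] result.
#' @param conf_level Confidence level for the odds-ratio interval.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `p_value`, `odds_ratio`, `or_low`, `or_high`.
#' @export
tidy.stepwise_logit <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  if (nrow(sm) < 2L) {
    return(tibble::tibble(
      term = character(), estimate = numeric(), std_error = numeric(),
      p_value = numeric(), odds_ratio = numeric(),
      or_low = numeric(), or_high = numeric()
    ))
  }
  sm <- sm[-1, , drop = FALSE]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = gsub("`", "", rownames(sm)),
    estimate = sm[, 1],
    std_error = sm[, 2],
    p_value = sm[, 4],
    odds_ratio = exp(sm[, 1]),
    or_low = exp(sm[, 1] - z * sm[, 2]),
    or_high = exp(sm[, 1] + z * sm[, 2])
  )
}

#' Model-level summary of a stepwise logistic fit
#'
#' @param x A [forward_stepwise_logistic()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_selected`, `deviance`,
#'   `null_deviance`, `aic`, `hl_statistic`, `hl_p`.
#' @export
glance.stepwise_logit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_selected = length(x$selected),
    deviance = x$fit$deviance,
    null_deviance = x$fit$null.deviance,
    aic = x$fit$aic,
    hl_statistic = if (is.null(x$hl)) NA_real_ else x$hl$statistic,
    hl_p = if (is.null(x$hl)) NA_real_ else x$hl$p_value
  )
}

#' @export
print.stepwise_logit <- function(x, ...) {
  cat(sprintf(
    "<stepwise_logit> n = %d, entry p < %.3g, removal p > %.3g\n",
    x$n, x$entry_p, x$removal_p
  ))
  if (length(x$selected) == 0L) {
    cat("  no feature entered the model\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
    print(tidy(x))
  }
  invisible(x)
}
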