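#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects into `n_groups` near-equal "deciles of risk" by fitted
#' probability (tied probabilities are never split across groups), then
#' compares observed and expected event counts with the chi-square statistic
#' `sum (O1 - E1)^2 / E1 + (O0 - E0)^2 / E0` on `g - 2` degrees of freedom,
#' `g` the number of groups actually used. Groups whose expected event or
#' non-event count is zero are merged into their neighbor (with a warning
#' and a corresponding df reduction). If fewer than 3 usable groups remain
#' (e.g. all probabilities identical) the statistic is degenerate and
#' `p_value = 1` is returned with a warning.
#'
#' @param probabilities Fitted event probabilities in `[0, 1]`.
#' @param labels Binary outcomes (0/1).
#' @param n_groups Number of risk groups (default 10).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n_groups_used`.
#' @export
#' @examples
#' set.seed(1)
#' p <- runif(200)
#' y <- rbinom(200, 1, p)
#' hosmer_lemeshow(p, y)
hosmer_lemeshow <- function(probabilities, labels, n_groups = 10L) {
  y <- as_binary_labels(labels)
  p <- as.numeric(probabilities)
  if (length(p) != length(y)) rlang::abort("probabilities and labels must have equal length")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) rlang::abort("probabilities must be in [0, 1]")
  n <- length(p)
  n_groups <- as.integer(n_groups)
  if (n < 2L * n_groups) rlang::abort("need at least 2 subjects per risk group")

  # group by rank of p, ties kept together via the maximal rank
  grp <- ceiling(rank(p, ties.method = "max") / n * n_groups)
  tab <- dplyr::tibble(grp = grp, y = y, p = p) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      m = dplyr::n(), o1 = sum(.data$y), e1 = sum(.data$p), .groups = "drop"
    ) |>
    dplyr::arrange(.data$grp)

  # merge groups with a zero expected cell into their lower neighbor
  merged_any <- FALSE
  i <- 1L
  while (i <= nrow(tab)) {
    e0 <- tab$m[i] - tab$e1[i]
    if ((tab$e1[i] == 0 || e0 == 0) && nrow(tab) > 1L) {
      j <- if (i == 1L) 2L else i - 1L
      tab$m[j] <- tab$m[j] + tab$m[i]
      tab$o1[j] <- tab$o1[j] + tab$o1[i]
      tab$e1[j] <- tab$e1[j] + tab$e1[i]
      tab <- tab[-i, ]
      merged_any <- TRUE
      i <- 1L
    } else {
      i <- i + 1L
    }
  }
  if (merged_any) {
    rlang::warn("risk groups with zero expected counts were merged; degrees of freedom reduced")
  }
  g <- nrow(tab)
  df <- g - 2L
  if (df < 1L) {
    rlang::warn("fewer than 3 usable risk groups; Hosmer-Lemeshow test is degenerate")
    return(tibble::tibble(statistic = 0, df = df, p_value = 1, n_groups_used = g))
  }
  e0 <- tab$m - tab$e1
  o0 <- tab$m - tab$o1
  statistic <- sum((tab$o1 - tab$e1)^2 / tab$e1 + (o0 - e0)^2 / e0)
  tibble::tibble(
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    n_groups_used = g
  )
}
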