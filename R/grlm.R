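# Gray-level run-length matrices and the four Galloway-type features
# (long run emphasis, run length non-uniformity, low gray-level run
# emphasis, short run low gray-level emphasis).

#' Gray-level run-length matrix for one direction
#'
#' Scans every maximal line of consecutive inside-mask pixels along the
#' direction and counts maximal runs of constant quantized gray level.
#' Outside-mask pixels break runs. Runs therefore partition the inside-mask
#' pixels traversed: `sum_j j * r(i, j)` equals the inside-pixel count for
#' every direction.
#'
#' @param roi A [normalize_quantize()] result.
#' @param direction One of `"0"`, `"45"`, `"90"`, `"135"` (degrees) or the
#'   corresponding `(delta_row, delta_col)` offset.
#' @return An object of class `grlm`: list with `counts` (Ng x Rmax matrix,
#'   row `i` = gray level `i - 1`, column `j` = run length `j`), `direction`,
#'   and `n_runs` (Nr, the total run count).
#' @export
#' @examples
#' img <- matrix(c(1, 1, 2, 3, 3, 3, 1, 2, 2), 3, 3, byrow = TRUE)
#' q <- structure(
#'   list(levels = img, mask = matrix(TRUE, 3, 3), n_levels = 4L),
#'   class = "quantized_roi"
#' )
#' grlm(q, "0")$n_runs # 5 runs: (1,2) (2,1) (3,3) (1,1) (2,2)
grlm <- function(roi, direction) {
  off <- resolve_offset(direction)
  lv <- roi$levels
  ng <- roi$n_levels
  rmax <- max(nrow(lv), ncol(lv))

  # group pixels into traversal lines; within each group, column-major order
  # visits consecutive pixels along the direction
  key <- if (identical(off, c(0L, 1L))) {
    row(lv)
  } else if (identical(off, c(-1L, 0L))) {
    col(lv)
  } else if (identical(off, c(-1L, 1L))) {
    row(lv) + col(lv) # anti-diagonals: col-major order steps (-1, +1)
  } else {
    col(lv) - row(lv) # diagonals: col-major order steps (+1, +1), same runs
  }
  lines <- split(as.vector(lv), as.vector(key))

  level_acc <- integer(0)
  len_acc <- integer(0)
  for (v in lines) {
    r <- rle(v) # NA values never merge, so outside-mask pixels break runs
    keep <- !is.na(r$values)
    if (any(keep)) {
      level_acc <- c(level_acc, r$values[keep])
      len_acc <- c(len_acc, r$lengths[keep])
    }
  }
  counts <- matrix(0, ng, rmax)
  if (length(level_acc) > 0L) {
    code <- level_acc * rmax + len_acc # 1-based: level*rmax + len
    tab <- tabulate(code, nbins = ng * rmax)
    counts <- matrix(tab, ng, rmax, byrow = TRUE)
  }
  structure(
    list(counts = counts, direction = off, n_runs = sum(counts)),
    class = "grlm"
  )
}

#' GRLM texture features for one direction
#'
#' Galloway run-length statistics with 1-based gray index `i` (quantized
#' level + 1, so the lowest level carries the largest low-gray weight
#' without division by zero) and run length `j`:
#' * `LRE = sum j^2 r(i, j) / Nr` — long run emphasis;
#' * `RLN = sum_j (sum_i r(i, j))^2 / Nr` — run length non-uniformity;
#' * `LGLRE = sum r(i, j) / i^2 / Nr` — low gray-level run emphasis;
#' * `SRLGLE = sum r(i, j) / (i^2 j^2) / Nr` — short run low gray-level
#'   emphasis.
#'
#' @param m A [grlm()] result with at least one run.
#' @return Named numeric vector `c(LRE, RLN, LGLRE, SRLGLE)`.
#' @export
grlm_features <- function(m) {
  nr_runs <- m$n_runs
  if (nr_runs < 1) rlang::abort("empty run-length matrix: no run in this direction")
  counts <- m$counts
  i <- seq_len(nrow(counts)) # 1-based gray index
  j <- seq_len(ncol(counts))
  rj <- colSums(counts)
  ri <- rowSums(counts)
  c(
    LRE = sum(j^2 * rj) / nr_runs,
    RLN = sum(rj^2) / nr_runs,
    LGLRE = sum(ri / i^2) / nr_runs,
    SRLGLE = sum(counts * outer(1 / i^2, 1 / j^2)) / nr_runs
  )
}
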