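# Gray-level co-occurrence matrices and the four Haralick-type features
# (contrast, energy/angular second moment, entropy, information measure of
# correlation) used for second-order texture description.

#' Pixel offsets for the four GLCM/GRLM directions
#'
#' Distance-1 offsets `(delta_row, delta_col)` for angles 0, 45, 90 and 135
#' degrees, in image convention (row increases downward).
#' @return Named list of length-2 integer vectors.
#' @export
texture_offsets <- function() {
  list(
    `0` = c(0L, 1L),
    `45` = c(-1L, 1L),
    `90` = c(-1L, 0L),
    `135` = c(-1L, -1L)
  )
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts pairs of quantized gray levels at the given distance-1 offset.
#' A pair contributes only when *both* pixels lie inside the ROI mask, and
#' each pair is accumulated in both orders, so the matrix is symmetric and
#' 0 degrees is equivalent to 180 degrees.
#'
#' @param roi A [normalize_quantize()] result.
#' @param offset Direction: one of `"0"`, `"45"`, `"90"`, `"135"` (degrees),
#'   or a length-2 integer `(delta_row, delta_col)` vector.
#' @return An object of class `glcm`: list with `counts` (Ng x Ng symmetric
#'   matrix), `p` (probabilities, counts normalized to sum 1), `offset`,
#'   `n_pairs`, and `empty` (TRUE when no valid pair exists in this
#'   direction, e.g. a one-pixel-thin mask at 45 degrees).
#' @export
#' @examples
#' img <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1, 0, 2, 2, 2, 2, 2, 3, 3), 4, 4, byrow = TRUE)
#' q <- list(
#'   levels = img, mask = matrix(TRUE, 4, 4),
#'   n_levels = 4L, mu = NA, sigma = NA
#' )
#' class(q) <- "quantized_roi"
#' glcm(q, "0")$counts
glcm <- function(roi, offset) {
  off <- resolve_offset(offset)
  lv <- roi$levels
  ng <- roi$n_levels
  nr <- nrow(lv); nc <- ncol(lv)
  dr <- off[1]; dc <- off[2]

  r1 <- seq_len(nr)
  c1 <- seq_len(nc)
  r1 <- r1[r1 + dr >= 1L & r1 + dr <= nr]
  c1 <- c1[c1 + dc >= 1L & c1 + dc <= nc]
  counts <- matrix(0, ng, ng)
  if (length(r1) > 0L && length(c1) > 0L) {
    a <- lv[r1, c1, drop = FALSE]
    b <- lv[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      code <- a[ok] * ng + b[ok] + 1 # row-level i, col-level j, 1-based code
      tab <- tabulate(code, nbins = ng * ng)
      one_way <- matrix(tab, ng, ng, byrow = TRUE)
      counts <- one_way + t(one_way)
    }
  }
  n_pairs <- sum(counts)
  structure(
    list(
      counts = counts,
      p = if (n_pairs > 0) counts / n_pairs else counts,
      offset = off,
      n_pairs = n_pairs,
      empty = n_pairs == 0
    ),
    class = "glcm"
  )
}

resolve_offset <- function(offset) {
  offs <- texture_offsets()
  if (is.character(offset) || is.numeric(offset) && length(offset) == 1L) {
    key <- as.character(offset)
    if (!key %in% names(offs)) {
      rlang::abort("offset must be one of 0, 45, 90, 135 (degrees) or a (drow, dcol) pair")
    }
    return(offs[[key]])
  }
  if (length(offset) == 2L) {
    off <- as.integer(offset)
    if (!any(vapply(offs, identical, logical(1), y = off))) {
      rlang::abort("offset must be a distance-1 offset among (0,1), (-1,1), (-1,0), (-1,-1)")
    }
    return(off)
  }
  rlang::abort("invalid offset")
}

#' GLCM texture features for one direction
#'
#' From the co-occurrence probabilities `p(i, j)` computes:
#' * `CON` — contrast, `sum (i - j)^2 p(i, j)`: local gray-level variation;
#' * `ENE` — energy (angular second moment), `sum p(i, j)^2`: uniformity of
#'   the gray-level distribution, 1 for a constant image;
#' * `ENT` — entropy, `-sum p log2 p` over nonzero cells: randomness of the
#'   intensity distribution;
#' * `INC` — information measure of correlation 1,
#'   `(HXY - HXY1) / max(HX, HY)` with `HXY` the joint entropy, `HXY1 =
#'   -sum p(i,j) log2(px(i) py(j))` and `HX`, `HY` the marginal entropies;
#'   0 when both marginal entropies vanish. The second variant
#'   `sqrt(1 - exp(-2 (HXY2 - HXY)))` is available via `variant = "imc2"`.
#'
#' @param m A [glcm()] result (must be non-empty).
#' @param log_base Base for the entropies (default 2; changing the base
#'   rescales ENT but leaves the INC ratio unchanged).
#' @param variant `"imc1"` (default) or `"imc2"` for the INC feature.
#' @return Named numeric vector `c(CON, ENE, ENT, INC)`.
#' @export
glcm_features <- function(m, log_base = 2, variant = c("imc1", "imc2")) {
  variant <- match.arg(variant)
  if (m$empty) rlang::abort("empty co-occurrence matrix: no valid pixel pair in this direction")
  p <- m$p
  ng <- nrow(p)
  nz <- which(p > 0, arr.ind = TRUE)
  pv <- p[nz]
  lg <- function(x) log(x, base = log_base)

  con <- sum((nz[, 1] - nz[, 2])^2 * pv)
  ene <- sum(pv^2)
  ent <- -sum(pv * lg(pv))

  px <- rowSums(p)
  py <- colSums(p)
  hx <- -sum(px[px > 0] * lg(px[px > 0]))
  hy <- -sum(py[py > 0] * lg(py[py > 0]))
  if (variant == "imc1") {
    hxy1 <- -sum(pv * lg(px[nz[, 1]] * py[nz[, 2]]))
    inc <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  } else {
    pxpy <- outer(px, py)
    hxy2 <- -sum(pxpy[pxpy > 0] * lg(pxpy[pxpy > 0]))
    inc <- sqrt(max(1 - exp(-2 * (hxy2 - ent)), 0))
  }
  c(CON = con, ENE = ene, ENT = ent, INC = inc)
}
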