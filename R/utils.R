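# Internal helpers: deterministic sub-seeds, separable Gaussian smoothing,
# 4-connected binary morphology and component labelling on small 2D masks.

# Deterministic sub-seed from (master seed, subject index, purpose tag).
# Multiplicative mixing mod a prime below 2^31 keeps the result a valid
# 32-bit seed and guarantees that adding subjects never reshuffles the
# streams of earlier ones.
subseed <- function(master, index, purpose) {
  p <- 2147483587 # largest prime < 2^31 - 60
  x <- (as.numeric(master) %% p)
  x <- (x * 69069 + as.numeric(index) * 1000003 + as.numeric(purpose) * 10007 + 12345) %% p
  x <- (x * 69069 + 7919) %% p
  as.integer(x)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so cohort generation does not disturb the session stream.
with_subseed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Truncated-Gaussian smoothing matrix: row i holds the (renormalized) kernel
# centred on i. Applying K on both sides (K %*% X %*% t(K)) smooths a field
# separably with reflect-free, renormalizing boundary handling.
gauss_kernel_matrix <- function(n, sigma) {
  stopifnot(sigma > 0)
  idx <- seq_len(n)
  K <- stats::dnorm(outer(idx, idx, "-"), sd = sigma)
  K / rowSums(K)
}

smooth_field <- function(z, sigma) {
  K <- gauss_kernel_matrix(nrow(z), sigma)
  if (ncol(z) != nrow(z)) {
    Kc <- gauss_kernel_matrix(ncol(z), sigma)
    K %*% z %*% t(Kc)
  } else {
    K %*% z %*% t(K)
  }
}

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

dilate4 <- function(mask, r = 1L) {
  m <- mask
  for (i in seq_len(r)) {
    m <- m | shift_mat(m, 1, 0) | shift_mat(m, -1, 0) |
      shift_mat(m, 0, 1) | shift_mat(m, 0, -1)
  }
  m
}

erode4 <- function(mask, r = 1L) {
  m <- mask
  for (i in seq_len(r)) {
    m <- m & shift_mat(m, 1, 0, TRUE) & shift_mat(m, -1, 0, TRUE) &
      shift_mat(m, 0, 1, TRUE) & shift_mat(m, 0, -1, TRUE)
  }
  m
}

# 4-connected component labelling by breadth-first search over pixel
# indices (frontier kept as an integer vector, neighbor lookup by index
# arithmetic with explicit border guards).
label4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- integer(nr * nc)
  inside <- as.vector(mask)
  current <- 0L
  todo <- which(inside & lab == 0L)
  while (length(todo) > 0L) {
    current <- current + 1L
    frontier <- todo[1L]
    lab[frontier] <- current
    while (length(frontier) > 0L) {
      rr <- (frontier - 1L) %% nr + 1L
      up <- frontier[rr > 1L] - 1L
      dn <- frontier[rr < nr] + 1L
      lf <- frontier[frontier > nr] - nr
      rt <- frontier[frontier <= nr * (nc - 1L)] + nr
      nb <- c(up, dn, lf, rt)
      nb <- unique(nb[inside[nb] & lab[nb] == 0L])
      lab[nb] <- current
      frontier <- nb
    }
    todo <- todo[lab[todo] == 0L]
  }
  matrix(lab, nr, nc)
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label4(mask)
  tt <- table(lab[lab > 0])
  keep <- as.integer(names(tt)[which.max(tt)])
  lab == keep
}

dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

rotate90 <- function(m) {
  # counter-clockwise rotation: first column becomes last row
  t(m)[ncol(m):1, , drop = FALSE]
}
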