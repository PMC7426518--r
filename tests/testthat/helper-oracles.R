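# Independent brute-force oracles. These re-derive co-occurrence counts,
# run enumerations, feature formulas and AUC by direct enumeration, sharing
# no code with the package implementation.

# Build a quantized_roi directly from a level matrix (NA = outside mask).
mk_qroi <- function(levels, ng = max(levels, na.rm = TRUE) + 1L) {
  structure(
    list(
      levels = levels, mask = !is.na(levels), n_levels = as.integer(ng),
      mu = NA_real_, sigma = NA_real_
    ),
    class = "quantized_roi"
  )
}

# Exhaustive pair enumeration: for every pixel, look at its offset neighbor;
# count the ordered pair in both orders when both are inside the mask.
oracle_glcm_counts <- function(levels, dr, dc, ng) {
  counts <- matrix(0, ng, ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- levels[r, c]; b <- levels[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
    }
  }
  counts
}

# Direct evaluation of the GLCM feature formulas by looping over cells.
oracle_glcm_features <- function(counts) {
  total <- sum(counts)
  p <- counts / total
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  con <- 0; ene <- 0; ent <- 0; hxy1 <- 0
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      if (p[i, j] > 0) {
        con <- con + (i - j)^2 * p[i, j]
        ene <- ene + p[i, j]^2
        ent <- ent - p[i, j] * log2(p[i, j])
        hxy1 <- hxy1 - p[i, j] * log2(px[i] * py[j])
      }
    }
  }
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  inc <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  c(CON = con, ENE = ene, ENT = ent, INC = inc)
}

# Walk every traversal line pixel by pixel, cutting runs at mask breaks and
# level changes. Directions given as (dr, dc) steps.
oracle_grlm_counts <- function(levels, dr, dc, ng, rmax = max(dim(levels))) {
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- matrix(0, ng, rmax)
  # starting pixels: those with no in-bounds predecessor along (dr, dc)
  starts <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      pr <- r - dr; pc <- c - dc
      if (pr < 1 || pr > nr || pc < 1 || pc > nc) starts[[length(starts) + 1]] <- c(r, c)
    }
  }
  for (st in starts) {
    r <- st[1]; c <- st[2]
    cur_level <- NA; cur_len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- levels[r, c]
      if (!is.na(v) && !is.na(cur_level) && v == cur_level) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_level)) counts[cur_level + 1, cur_len] <- counts[cur_level + 1, cur_len] + 1
        cur_level <- v
        cur_len <- if (is.na(v)) 0 else 1
      }
      r <- r + dr; c <- c + dc
    }
    if (!is.na(cur_level)) counts[cur_level + 1, cur_len] <- counts[cur_level + 1, cur_len] + 1
  }
  counts
}

oracle_grlm_features <- function(counts) {
  nr_runs <- sum(counts)
  lre <- 0; lglre <- 0; srlgle <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      if (counts[i, j] > 0) {
        lre <- lre + j^2 * counts[i, j]
        lglre <- lglre + counts[i, j] / i^2
        srlgle <- srlgle + counts[i, j] / (i^2 * j^2)
      }
    }
  }
  rln <- sum(colSums(counts)^2)
  c(LRE = lre / nr_runs, RLN = rln / nr_runs,
    LGLRE = lglre / nr_runs, SRLGLE = srlgle / nr_runs)
}

oracle_histogram <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  c(SKE = m3 / m2^1.5, KUR = m4 / m2^2)
}

# Ten-feature oracle: histogram on inside pixels, second-order families
# averaged over the directions that contain at least one pair / run.
oracle_extract_features <- function(levels, ng) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  gl <- list(); gr <- list()
  for (o in offs) {
    cc <- oracle_glcm_counts(levels, o[1], o[2], ng)
    if (sum(cc) > 0) gl[[length(gl) + 1]] <- oracle_glcm_features(cc)
    rc <- oracle_grlm_counts(levels, o[1], o[2], ng)
    if (sum(rc) > 0) gr[[length(gr) + 1]] <- oracle_grlm_features(rc)
  }
  c(
    oracle_histogram(levels[!is.na(levels)]),
    colMeans(do.call(rbind, gl)),
    colMeans(do.call(rbind, gr))
  )
}

# AUC as the exhaustive concordant-pair fraction (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_mw_exact_p <- function(g0, g1) {
  pooled <- c(g0, g1)
  n0 <- length(g0)
  u_stat <- function(a, b) {
    s <- 0
    for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
    s
  }
  u_obs <- u_stat(g0, g1)
  idx <- utils::combn(length(pooled), n0)
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  mu <- n0 * (length(pooled) - n0) / 2
  # two-sided: arrangements at least as extreme in |U - E[U]|
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Fisher exact p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - amin + 1]
  sum(probs[probs <= p_obs + 1e-12])
}

# Random small test image: levels in 0..(ng-1), random mask with at least
# min_px inside pixels.
random_level_image <- function(nr, nc, ng, p_mask = 0.8, min_px = 3) {
  repeat {
    lv <- matrix(sample(0:(ng - 1), nr * nc, replace = TRUE), nr, nc)
    mask <- matrix(stats::runif(nr * nc) < p_mask, nr, nc)
    if (sum(mask) >= min_px) {
      lv[!mask] <- NA_integer_
      return(lv)
    }
  }
}
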