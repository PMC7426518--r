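# Texture features: hand-enumerated examples, brute-force oracle
# equivalence, analytic limits, invariances and error isolation.

test_that("GLCM counts on the 4x4 worked example match the enumeration", {
  img <- matrix(c(
    0, 0, 1, 1,
    0, 0, 1, 1,
    0, 2, 2, 2,
    2, 2, 3, 3
  ), 4, 4, byrow = TRUE)
  q <- mk_qroi(img, ng = 4)
  g <- glcm(q, "0")
  expected <- matrix(0, 4, 4)
  expected[1, 1] <- 4; expected[1, 2] <- expected[2, 1] <- 2
  expected[2, 2] <- 4; expected[1, 3] <- expected[3, 1] <- 1
  expected[3, 3] <- 6; expected[3, 4] <- expected[4, 3] <- 1
  expected[4, 4] <- 2
  expect_equal(g$counts, expected, ignore_attr = TRUE)
  expect_equal(g$n_pairs, 24)
  expect_equal(sum(g$p), 1)
  expect_true(isSymmetric(g$counts))
  # features agree with the direct formula evaluation on the same counts
  expect_equal(glcm_features(g), oracle_glcm_features(expected), tolerance = 1e-12)
})

test_that("a constant image gives the degenerate GLCM feature limits", {
  q <- mk_qroi(matrix(3L, 5, 5), ng = 8)
  for (d in c("0", "45", "90", "135")) {
    f <- glcm_features(glcm(q, d))
    expect_equal(f, c(CON = 0, ENE = 1, ENT = 0, INC = 0))
  }
})

test_that("entropy equals log2(k) for k equiprobable cells", {
  # 1xN alternating stripes: 0,1,0,1 ... at 0 degrees gives two symmetric
  # off-diagonal cells with p = 1/2 each
  img <- matrix(rep(c(0L, 1L), 8), 1, 16)
  f <- glcm_features(glcm(mk_qroi(img, ng = 2), "0"))
  expect_equal(unname(f["ENT"]), 1) # log2(2)
  q4 <- mk_qroi(matrix(c(0L, 1L, 2L, 3L), 1, 4), ng = 4)
  f4 <- glcm_features(glcm(q4, "0"))
  expect_equal(unname(f4["ENT"]), log2(6)) # 6 equiprobable cells
})

test_that("masked GLCM equals brute-force enumeration restricted to the mask", {
  img <- matrix(c(
    0, 0, 1, 1,
    0, 0, 1, 1,
    0, 2, 2, 2,
    2, 2, 3, 3
  ), 4, 4, byrow = TRUE)
  img[2, 3] <- NA # exclude one pixel
  q <- mk_qroi(img, ng = 4)
  offs <- texture_offsets()
  for (d in names(offs)) {
    expect_equal(
      glcm(q, d)$counts,
      oracle_glcm_counts(img, offs[[d]][1], offs[[d]][2], 4),
      ignore_attr = TRUE
    )
  }
})

test_that("GRLM on the 3x3 worked example enumerates the five runs", {
  img <- matrix(c(
    1, 1, 2,
    3, 3, 3,
    1, 2, 2
  ), 3, 3, byrow = TRUE)
  q <- mk_qroi(img, ng = 4)
  r <- grlm(q, "0")
  expect_equal(r$n_runs, 5)
  expected <- matrix(0, 4, 3)
  expected[2, 2] <- 1 # (1,2)
  expected[3, 1] <- 1 # (2,1)
  expected[4, 3] <- 1 # (3,3)
  expected[2, 1] <- 1 # (1,1)
  expected[3, 2] <- 1 # (2,2)
  expect_equal(r$counts, expected, ignore_attr = TRUE)
  f <- grlm_features(r)
  expect_equal(unname(f["LRE"]), 3.8) # (4+1+9+1+4)/5
  expect_equal(f, oracle_grlm_features(expected), tolerance = 1e-12)
})

test_that("run-length formula collapses behave as expected", {
  # constant row: one run of length n
  q <- mk_qroi(matrix(0L, 1, 7), ng = 2)
  r <- grlm(q, "0")
  expect_equal(r$n_runs, 1)
  f <- grlm_features(r)
  expect_equal(unname(f["LRE"]), 49)
  expect_equal(unname(f["LGLRE"]), 1)    # lowest level, index 1
  expect_equal(unname(f["SRLGLE"]), 1 / 49)

  # all runs of length 1: LRE = 1, RLN = Nr
  q2 <- mk_qroi(matrix(c(0L, 1L, 0L, 1L, 0L), 1, 5), ng = 2)
  r2 <- grlm(q2, "0")
  f2 <- grlm_features(r2)
  expect_equal(unname(f2["LRE"]), 1)
  expect_equal(unname(f2["RLN"]), r2$n_runs)
})

test_that("runs partition the inside-mask pixels in every direction", {
  set.seed(12)
  for (rep in 1:20) {
    lv <- random_level_image(7, 7, 4)
    q <- mk_qroi(lv, ng = 4)
    px <- sum(!is.na(lv))
    for (d in c("0", "45", "90", "135")) {
      counts <- grlm(q, d)$counts
      expect_equal(sum(sweep(counts, 2, seq_len(ncol(counts)), "*")), px)
    }
  }
})

test_that("histogram features match direct moment computation", {
  expect_equal(unname(histogram_features(mk_qroi(matrix(c(1L, 2L, 3L), 1, 3), ng = 4))["SKE"]), 0)
  expect_equal(unname(histogram_features(mk_qroi(matrix(c(1L, 1L, 2L, 2L), 1, 4), ng = 4))["KUR"]), 1)
  set.seed(13)
  lv <- random_level_image(6, 6, 5)
  expect_equal(
    histogram_features(mk_qroi(lv, ng = 5)),
    oracle_histogram(lv[!is.na(lv)]),
    tolerance = 1e-12
  )
})

test_that("kurtosis of a large quantized normal field approaches 3", {
  set.seed(14)
  img <- matrix(rnorm(300 * 300), 300, 300)
  q <- normalize_quantize(img, matrix(TRUE, 300, 300), n_levels = 256)
  f <- histogram_features(q)
  expect_equal(unname(f["KUR"]), 3, tolerance = 0.05)
  expect_equal(unname(f["SKE"]), 0, tolerance = 0.05)
})

test_that("constant ROI isolates the histogram error while second-order features remain", {
  q <- mk_qroi(matrix(2L, 6, 6), ng = 4)
  expect_error(histogram_features(q), "undefined histogram moments")
  expect_warning(f <- extract_features(q), "histogram features undefined")
  expect_true(is.na(f["SKE"]) && is.na(f["KUR"]))
  expect_equal(unname(f["ENE"]), 1)
  expect_equal(unname(f["ENT"]), 0)
  expect_equal(unname(f["LGLRE"]), 1 / 9) # all pixels at level 2, index 3
})

test_that("direction-averaged features are invariant to 90-degree rotation", {
  set.seed(15)
  for (rep in 1:10) {
    lv <- random_level_image(8, 8, 4, min_px = 12)
    rot <- texturestager:::rotate90(lv)
    f1 <- suppressWarnings(extract_features(mk_qroi(lv, ng = 4)))
    f2 <- suppressWarnings(extract_features(mk_qroi(rot, ng = 4)))
    expect_equal(f1, f2, tolerance = 1e-10)
  }
})

test_that("thin masks drop empty 45/135-degree directions from the mean", {
  lv <- matrix(NA_integer_, 3, 5)
  lv[2, ] <- c(0L, 1L, 1L, 0L, 2L) # single row: no diagonal or vertical pair
  q <- mk_qroi(lv, ng = 4)
  expect_true(glcm(q, "45")$empty)
  expect_true(glcm(q, "90")$empty)
  f <- extract_features(q)
  horizontal_only <- glcm_features(glcm(q, "0"))
  expect_equal(f[c("CON", "ENE", "ENT", "INC")], horizontal_only)
})

test_that("full feature vector matches the oracle on the 4x4 worked example", {
  img <- matrix(c(
    0, 0, 1, 1,
    0, 0, 1, 1,
    0, 2, 2, 2,
    2, 2, 3, 3
  ), 4, 4, byrow = TRUE)
  f <- extract_features(mk_qroi(img, ng = 4))
  expect_equal(f, oracle_extract_features(img, 4), tolerance = 1e-10)
})

test_that("features are invariant to positive affine transforms of raw intensities", {
  set.seed(16)
  for (rep in 1:10) {
    img <- matrix(runif(256, 100, 900), 16, 16)
    mask <- matrix(runif(256) < 0.85, 16, 16)
    a <- runif(1, 0.2, 8); b <- runif(1, -100, 100)
    f1 <- extract_features(normalize_quantize(img, mask, 16))
    f2 <- extract_features(normalize_quantize(a * img + b, mask, 16))
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})
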