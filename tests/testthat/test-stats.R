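# Univariate screening, categorical tests, ICC and Spearman correlation.

test_that("small untied samples get the exact Mann-Whitney p-value", {
  res <- compare_groups(c(1, 2, 3, 4), c(0, 0, 1, 1), test = "mann-whitney")
  expect_equal(res$test_used, "mann-whitney")
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$summary_type, "median_iqr")
})

test_that("Mann-Whitney p equals the exact permutation p for small groups", {
  set.seed(20)
  for (rep in 1:15) {
    n0 <- sample(3:8, 1); n1 <- sample(3:8, 1)
    g0 <- rnorm(n0); g1 <- rnorm(n1, mean = runif(1, -1, 1))
    res <- compare_groups(c(g0, g1), rep(c(0, 1), c(n0, n1)), test = "mann-whitney")
    expect_equal(res$test_used, "mann-whitney")
    expect_equal(res$p_value, oracle_mw_exact_p(g0, g1), tolerance = 1e-9)
  }
})

test_that("identical normal groups take the t-test path with p = 1", {
  set.seed(21)
  g <- rnorm(30)
  res <- compare_groups(c(g, g), rep(c(0, 1), each = 30))
  expect_equal(res$test_used, "t-test")
  expect_equal(res$summary_type, "mean_sd")
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_equal(res$center_0, res$center_1)
})

test_that("a zero-variance group forces the Mann-Whitney path", {
  res <- compare_groups(c(5, 5, 5, 5, 5, 1, 2, 3, 4, 6),
                        rep(c(0, 1), each = 5))
  expect_equal(res$test_used, "mann-whitney")
})

test_that("heavy-tailed data fails the normality gate", {
  set.seed(22)
  g0 <- exp(rnorm(60, sd = 2)); g1 <- exp(rnorm(60, sd = 2))
  res <- compare_groups(c(g0, g1), rep(c(0, 1), each = 60))
  expect_equal(res$test_used, "mann-whitney")
})

test_that("the categorical test picks chi-square or Fisher by expected counts", {
  res <- categorical_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$test_used, "chi-square")
  expect_equal(res$p_value, 1)

  tab <- matrix(c(1, 8, 9, 2), 2) # expected counts < 5
  res2 <- categorical_test(tab)
  expect_equal(res2$test_used, "fisher")
  expect_equal(res2$p_value, oracle_fisher_p(tab), tolerance = 1e-9)

  tab3 <- matrix(c(20, 25, 30, 28, 22, 26), 2) # 2x3, all expected >= 5
  expect_equal(categorical_test(tab3)$test_used, "chi-square")

  expect_error(categorical_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("ICC is 1 for duplicated readers and banded as excellent", {
  x <- c(3.2, 4.1, 5.5, 2.2, 7.8)
  res <- icc_two_readers(x, x)
  expect_equal(res$icc, 1)
  expect_equal(res$band, "excellent")
  expect_false(res$trivial)

  res0 <- icc_two_readers(rep(2, 5), rep(2, 5))
  expect_equal(res0$icc, 1)
  expect_true(res0$trivial)
})

test_that("absolute agreement penalizes a constant shift between readers", {
  x <- c(1, 2, 3, 4, 5)
  res <- icc_two_readers(x, x + 2)
  expect_lt(res$icc, 1)
  # closed-form two-way ANOVA on this 5-subject example: subject variance
  # MSR = 5, MSE = 0, rater mean square MSC = n c^2 / 2 ... = 10
  # ICC = (5 - 0) / (5 + 0 + 2 * (10 - 0) / 5) = 5 / 9
  expect_equal(res$icc, 5 / 9, tolerance = 1e-12)
})

test_that("independent readers give ICC near zero", {
  set.seed(23)
  r1 <- rnorm(200); r2 <- rnorm(200)
  expect_lt(abs(icc_two_readers(r1, r2)$icc), 0.15)
})

test_that("agreement bands split exactly at 0.4, 0.6 and 0.8", {
  expect_equal(icc_band(c(0, 0.4, 0.41, 0.6, 0.61, 0.8, 0.81, 1)),
               c("poor", "poor", "moderate", "moderate",
                 "good", "good", "excellent", "excellent"))
})

test_that("ICC recovers the simulated reliability of a two-way random model", {
  set.seed(24)
  n <- 500
  sd_subject <- 1; sd_rater <- 0.2; sd_error <- 0.5
  truth <- sd_subject^2 / (sd_subject^2 + sd_rater^2 + sd_error^2)
  # the rater component has one df per replicate with k = 2 readers, so
  # recovery is judged on the replicate mean
  est <- vapply(1:20, function(i) {
    subj <- rnorm(n, sd = sd_subject)
    rater_eff <- rnorm(2, sd = sd_rater)
    icc_two_readers(
      subj + rater_eff[1] + rnorm(n, sd = sd_error),
      subj + rater_eff[2] + rnorm(n, sd = sd_error)
    )$icc
  }, numeric(1))
  expect_equal(mean(est), truth, tolerance = 0.05)
})

test_that("Spearman correlation with the class hits the rank-formula bound", {
  # values perfectly ordered by class: r_s equals the correlation of the
  # midranks, the maximal attainable value for this class balance
  labels <- rep(c(0, 1), c(6, 4))
  values <- c(1:6, 7:10)
  r <- spearman_with_class(values, labels)
  expect_equal(r, cor(rank(values), rank(labels)), tolerance = 1e-12)
  expect_equal(r, suppressWarnings(cor.test(values, labels, method = "spearman")$estimate[[1]]))

  set.seed(25)
  vals <- rnorm(500)
  labs <- rep(c(0, 1), each = 250)
  expect_lt(abs(spearman_with_class(vals, labs)), 0.1)

  expect_error(spearman_with_class(rep(1, 10), rep(c(0, 1), 5)), "constant")
  expect_error(spearman_with_class(rnorm(10), rep(0, 10)), "both classes")
})

test_that("univariate_screen flags each feature and carries Spearman r", {
  set.seed(26)
  n <- 40
  tbl <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    class_label = rep(c(0L, 1L), each = n / 2),
    sagittal_ENE = rnorm(n, mean = rep(c(1, 0), each = n / 2), sd = 0.3),
    sagittal_SKE = rnorm(n)
  )
  res <- univariate_screen(tbl)
  expect_equal(res$feature_name, c("sagittal_ENE", "sagittal_SKE"))
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  expect_true(all(is.finite(res$spearman_r)))
  expect_lt(res$spearman_r[1], 0) # higher ENE in class 0
})
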