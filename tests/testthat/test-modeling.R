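# Stepwise logistic selection, Hosmer-Lemeshow calibration, ROC analysis
# and the scope-wise model suite.

sim_signal_data <- function(n = 200, seed = 1, beta = 2.5) {
  set.seed(seed)
  x_signal <- rnorm(n)
  eta <- -0.2 + beta * x_signal
  tibble::tibble(
    y = rbinom(n, 1, stats::plogis(eta)),
    signal = x_signal,
    noise = rnorm(n)
  )
}

test_that("stepwise with a single candidate reduces to a plain LR test", {
  d <- sim_signal_data(120, seed = 2)
  fit <- forward_stepwise_logistic(d, "y", "signal")
  full <- glm(y ~ signal, binomial, d)
  null <- glm(y ~ 1, binomial, d)
  lr_p <- pchisq(null$deviance - full$deviance, 1, lower.tail = FALSE)
  expect_equal(fit$selected, "signal")
  expect_equal(fit$steps$p_value[1], lr_p, tolerance = 1e-10)
  expect_equal(unname(coef(fit$fit)), unname(coef(full)), tolerance = 1e-8)

  d_null <- d; d_null$signal <- rnorm(nrow(d), sd = 1e-3) * 0 + rnorm(nrow(d))
  set.seed(3); d_null$y <- rbinom(nrow(d), 1, 0.5)
  fit_null <- forward_stepwise_logistic(d_null, "y", "signal")
  p_single <- pchisq(
    glm(y ~ 1, binomial, d_null)$deviance - glm(y ~ signal, binomial, d_null)$deviance,
    1, lower.tail = FALSE
  )
  expect_equal(length(fit_null$selected) == 1, p_single < 0.05)
})

test_that("the informative feature is selected and the noise feature usually is not", {
  hits <- vapply(1:20, function(s) {
    d <- sim_signal_data(200, seed = 100 + s)
    fit <- forward_stepwise_logistic(d, "y", c("signal", "noise"))
    "signal" %in% fit$selected
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a binary predictor's coefficient equals the contingency log odds ratio", {
  d <- tibble::tibble(
    y = rep(c(0, 0, 1, 1), c(30, 10, 12, 28)),
    x = rep(c(0, 1, 0, 1), c(30, 10, 12, 28))
  )
  # two distinct fitted probabilities make the automatic calibration test
  # degenerate; that warning is expected here
  fit <- suppressWarnings(forward_stepwise_logistic(d, "y", "x"))
  lor <- log((28 * 30) / (10 * 12)) # log OR of the 2x2 table
  expect_equal(unname(coef(fit$fit)["x"]), lor, tolerance = 1e-8)
  td <- tidy(fit)
  expect_equal(td$odds_ratio, exp(lor), tolerance = 1e-8)
  expect_equal(td$or_low, exp(lor - qnorm(0.975) * td$std_error), tolerance = 1e-10)
})

test_that("the logistic MLE matches an independent Newton iteration on a tiny dataset", {
  d <- tibble::tibble(
    y = c(0, 1, 0, 0, 1, 1),
    x = c(-1.2, -0.5, 0.3, 0.1, 0.8, 1.5)
  )
  X <- cbind(1, d$x)
  beta <- c(0, 0)
  for (i in 1:50) {
    p <- 1 / (1 + exp(-X %*% beta))
    W <- as.vector(p * (1 - p))
    g <- t(X) %*% (d$y - p)
    H <- t(X) %*% (X * W)
    beta <- beta + solve(H, g)
    if (sqrt(sum(g^2)) < 1e-12) break
  }
  fit <- glm(y ~ x, binomial, d, control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), as.vector(beta), tolerance = 1e-6)
})

test_that("perfect separation is flagged rather than silently reported", {
  d <- tibble::tibble(y = rep(c(0, 1), each = 12), x = c(rnorm(12, -4), rnorm(12, 4)))
  expect_warning(
    fit <- forward_stepwise_logistic(d, "y", "x"),
    "separation|fewer than 10"
  )
  expect_true(any(fit$separation))
})

test_that("Hosmer-Lemeshow statistic matches a hand-computed decile table", {
  # 20 subjects, 5 groups of 4 with known probabilities
  p <- rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 4)
  y <- c(0, 0, 0, 1, 0, 0, 1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 1)
  res <- hosmer_lemeshow(p, y, n_groups = 5)
  # manual tabulation: per group m = 4, E1 = 4 * p, O1 observed events
  o1 <- c(1, 2, 2, 3, 4); e1 <- 4 * c(0.1, 0.3, 0.5, 0.7, 0.9)
  stat <- sum((o1 - e1)^2 / e1 + ((4 - o1) - (4 - e1))^2 / (4 - e1))
  expect_equal(res$statistic, stat, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, pchisq(stat, 3, lower.tail = FALSE))
})

test_that("constant probabilities give a degenerate calibration test with p = 1", {
  expect_warning(
    res <- hosmer_lemeshow(rep(0.5, 40), rep(c(0, 1), 20)),
    "degenerate"
  )
  expect_equal(res$p_value, 1)
})

test_that("ties in fitted probabilities are never split across risk groups", {
  p <- c(rep(0.2, 15), rep(0.8, 15))
  y <- rbinom(30, 1, p)
  res <- suppressWarnings(hosmer_lemeshow(p, y, n_groups = 10))
  expect_lte(res$n_groups_used, 2)
})

test_that("ROC handles perfect separation and matches the concordance oracle", {
  r <- roc_analysis(c(0.9, 0.8, 0.2, 0.3), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$accuracy, 100)
  expect_equal(r$direction, ">")

  set.seed(30)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    scores <- round(rnorm(n), 1) # rounding induces ties
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    got <- suppressWarnings(roc_analysis(scores, labels))
    ora <- oracle_auc(scores, labels)
    expect_equal(got$auc, max(ora, 1 - ora), tolerance = 1e-10)
  }
})

test_that("the Youden cutoff maximizes J with ties broken toward sensitivity", {
  scores <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.9)
  labels <- c(0, 0, 1, 0, 1, 1)
  r <- roc_analysis(scores, labels)
  co <- r$curve
  j <- co$sensitivity + co$specificity - 1
  expect_equal(r$sensitivity / 100 + r$specificity / 100 - 1, max(j), tolerance = 1e-12)
  best_j <- which(abs(j - max(j)) < 1e-12)
  expect_equal(r$sensitivity / 100, max(co$sensitivity[best_j]), tolerance = 1e-12)
})

test_that("random labels give a null AUC near one half", {
  set.seed(31)
  scores <- rnorm(500)
  labels <- sample(rep(c(0, 1), 250))
  expect_lt(abs(roc_analysis(scores, labels)$auc - 0.5), 0.05)
})

test_that("constant scores yield a flagged degenerate ROC", {
  expect_warning(r <- roc_analysis(rep(1, 20), rep(c(0, 1), 10)), "degenerate")
  expect_equal(r$auc, 0.5)
  expect_true(r$degenerate)
  expect_true(is.na(r$youden_cutoff))
})

test_that("the model suite unions candidates and honors signal placement", {
  set.seed(32)
  n <- 120
  tbl <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:n),
    class_label = rep(c(0L, 1L), each = n / 2),
    sagittal_SKE = rnorm(n),
    sagittal_KUR = rnorm(n),
    axial_ENE = rnorm(n, mean = rep(c(0, -1.2), each = n / 2), sd = 0.5),
    axial_ENT = rnorm(n, mean = rep(c(0, 1.0), each = n / 2), sd = 0.5)
  )
  uni <- univariate_screen(tbl)
  expect_warning(
    suite <- run_model_suite(tbl, uni),
    "sagittal" # no significant sagittal candidate
  )
  expect_setequal(suite$scope, c("axial", "combined"))
  ax <- suite[suite$scope == "axial", ]
  expect_true(all(startsWith(ax$candidates[[1]], "axial_")))
  expect_true(length(ax$model[[1]]$selected) >= 1)
  comb <- suite[suite$scope == "combined", ]
  expect_setequal(
    comb$candidates[[1]],
    uni$feature_name[uni$significant]
  )
  g <- glance(suite)
  expect_true(all(c("auc", "cutoff_rule", "sensitivity", "specificity",
                    "accuracy", "hl_p", "n_selected") %in% names(g)))
  td <- tidy(suite)
  expect_true(all(c("scope", "term", "odds_ratio", "or_low", "or_high",
                    "p_value") %in% names(td)))
})
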