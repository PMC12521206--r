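test_that("DeLong AUROC equals exhaustive pairwise concordance", {
  set.seed(81)
  for (k in 1:25) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    s <- round(rnorm(n), 1)              # rounding induces ties
    res <- auroc_delong(y, s)
    expect_equal(res$auc, oracle_auc(y, s), tolerance = 1e-12)
    expect_true(res$ci95[1] <= res$auc && res$auc <= res$ci95[2])
  }
})

test_that("AUROC honours degenerate and monotone-transformed inputs", {
  y <- rep(c(0, 1), each = 10)
  perfect <- c(rnorm(10, -5), rnorm(10, 5))
  expect_equal(suppressWarnings(auroc_delong(y, perfect))$auc, 1.0)
  expect_equal(suppressWarnings(auroc_delong(y, rep(0.5, 20)))$auc, 0.5)
  expect_error(auroc_delong(rep(1, 10), rnorm(10)), "both outcome classes")
  set.seed(82)
  s <- rnorm(20)
  expect_equal(auroc_delong(y, s)$auc, auroc_delong(y, exp(s))$auc,
               tolerance = 1e-12)
})

test_that("paired DeLong comparison is reflexive and symmetric", {
  set.seed(83)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  p1 <- runif(60); p2 <- runif(60)
  self <- delong_compare(y, p1, p1)
  expect_equal(self$difference, 0)
  expect_equal(self$p, 1)
  ab <- delong_compare(y, p1, p2); ba <- delong_compare(y, p2, p1)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$difference, -ba$difference, tolerance = 1e-12)
})

test_that("DeLong comparison separates informative from random predictors", {
  set.seed(84)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  informative <- y + rnorm(n, sd = 0.7)
  noise <- rnorm(n)
  res <- delong_compare(y, informative, noise)
  expect_lt(res$p, 0.05)
  expect_gt(res$auc1, res$auc2)
})

test_that("paired DeLong type-I error is near nominal for null predictors", {
  set.seed(85)
  n_sim <- 200; rej <- 0; rej_nested <- 0
  for (k in seq_len(n_sim)) {
    n <- 300
    x <- rnorm(n); y <- rbinom(n, 1, plogis(0.8 * x)); z <- rnorm(n)
    # two predictors unrelated to outcome, paired on the same subjects
    p <- delong_compare(y, rnorm(n), rnorm(n))$p
    if (p < 0.05) rej <- rej + 1
    # nested fitted models with a pure-noise addition: the AUC difference
    # is degenerate under H0, so the test must at least stay conservative
    f1 <- fitted(glm(y ~ x, family = binomial()))
    f2 <- fitted(glm(y ~ x + z, family = binomial()))
    pn <- tryCatch(delong_compare(y, f1, f2)$p, error = function(e) 1)
    if (!is.na(pn) && pn < 0.05) rej_nested <- rej_nested + 1
  }
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rej / n_sim - 0.05), 3 * se)
  expect_lte(rej_nested / n_sim, 0.05)
})

test_that("Hosmer-Lemeshow is zero on perfectly calibrated bins", {
  y <- c(rep(c(1, 0), c(5, 15)), rep(c(1, 0), c(15, 5)))
  probs <- rep(c(0.25, 0.75), each = 20)
  hl <- hosmer_lemeshow(y, probs, n_bins = 2)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow matches a hand-computed 20-observation example", {
  probs <- rep(c(0.2, 0.7), each = 10)
  y <- c(rep(c(1, 0), c(3, 7)), rep(c(1, 0), c(6, 4)))
  hl <- hosmer_lemeshow(y, probs, n_bins = 2)
  # bin 1: O1=3, E1=2, O0=7, E0=8; bin 2: O1=6, E1=7, O0=4, E0=3
  hand <- (3 - 2)^2 / 2 + (7 - 8)^2 / 8 + (6 - 7)^2 / 7 + (4 - 3)^2 / 3
  expect_equal(hl$statistic, hand, tolerance = 1e-10)
  expect_equal(hl$n_bins, 2)
  expect_error(hosmer_lemeshow(y, probs, n_bins = 11), "n >= 2")
})

test_that("Hosmer-Lemeshow rejects a well-calibrated model at ~nominal rate", {
  set.seed(86)
  n_sim <- 200; rej <- 0
  for (k in seq_len(n_sim)) {
    n <- 400
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
    probs <- fitted(glm(y ~ x, family = binomial()))
    if (hosmer_lemeshow(y, probs, 10)$p < 0.05) rej <- rej + 1
  }
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rej / n_sim - 0.05), 3 * se)
})

test_that("confusion metrics satisfy their accounting identities", {
  set.seed(87)
  y <- rbinom(92, 1, 0.5)
  probs <- runif(92)
  cm <- confusion_metrics(y, probs, 0.5)
  n <- length(y)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
  expect_equal(cm$accuracy * n, cm$tp + cm$tn, tolerance = 1e-12)
  expect_equal(cm$ppv * (cm$tp + cm$fp), cm$tp, tolerance = 1e-12)
  expect_equal(cm$npv * (cm$tn + cm$fn), cm$tn, tolerance = 1e-12)
  # worked cells: TP=24 FN=24 FP=20 TN=24
  y2 <- rep(c(1, 1, 0, 0), c(24, 24, 20, 24))
  p2 <- rep(c(0.9, 0.1, 0.9, 0.1), c(24, 24, 20, 24))
  cm2 <- confusion_metrics(y2, p2, 0.5)
  expect_equal(cm2$accuracy, 48 / 92, tolerance = 1e-12)
  expect_equal(cm2$sensitivity, 0.5, tolerance = 1e-12)
  expect_equal(cm2$ppv, 24 / 44, tolerance = 1e-12)
  # threshold 0 predicts everything positive
  cm0 <- confusion_metrics(y, probs, 0)
  expect_equal(cm0$sensitivity, 1)
  expect_equal(cm0$specificity, 0)
  # perfect predictions
  cm_perf <- confusion_metrics(y2, ifelse(y2 == 1, 0.9, 0.1), 0.5)
  expect_equal(cm_perf$accuracy, 1)
  expect_equal(cm_perf$sensitivity, 1)
  expect_equal(cm_perf$ppv, 1)
})

test_that("the calibration plot shares bins with Hosmer-Lemeshow", {
  set.seed(88)
  n <- 200
  probs <- runif(n)
  y <- rbinom(n, 1, probs)
  f <- file.path(tempdir(), "cal.png")
  tab <- calibration_plot(y, probs, f, n_bins = 10)
  expect_true(file.exists(f))
  expect_true(file.exists(file.path(tempdir(), "cal.csv")))
  hl <- hosmer_lemeshow(y, probs, 10)
  expect_equal(tab$expected, hl$table$expected, tolerance = 1e-12)
  expect_equal(tab$observed, hl$table$observed)
  # deterministic numeric table on re-run
  tab2 <- calibration_plot(y, probs, f, n_bins = 10)
  expect_identical(tab, tab2)
  # perfectly calibrated input sits on the identity line
  y3 <- rep(c(1, 0, 1, 0), c(2, 8, 8, 2))
  p3 <- rep(c(0.2, 0.8), each = 10)
  tab3 <- calibration_plot(y3, p3, f, n_bins = 2)
  expect_equal(tab3$obs_rate, tab3$exp_rate, tolerance = 1e-12)
})

test_that("the performance report is internally consistent", {
  set.seed(89)
  n <- 120
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  probs <- fitted(glm(y ~ x, family = binomial()))
  rep <- performance_report(y, probs, "demo")
  expect_equal(rep$auroc, auroc_delong(y, probs)$auc)
  expect_equal(rep$hl_statistic, hosmer_lemeshow(y, probs, 10)$statistic)
  cm <- rep$confusion
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
  expect_true(rep$auroc >= 0 && rep$auroc <= 1)
})
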