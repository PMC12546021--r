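test_that("F1 from printed precision/sensitivity pairs matches the reported cells", {
  # ileocecal-class cell printed as 92.59; the printed precision/sensitivity
  # pair gives 92.5815 (the cell was evidently computed before rounding its
  # inputs), so agreement is asserted to one unit in the last printed digit
  expect_equal(f1_score(99.97, 86.21), 92.59, tolerance = 0.01 / 92.59)
  # instrument-class pair reproduces 96.1 exactly at one decimal
  expect_equal(round(f1_score(94.07, 98.23), 1), 96.1)
})

test_that("scalar metrics follow the one-vs-rest formulas", {
  m <- class_metrics(confusion_counts(tp = 40, tn = 30, fp = 20, fn = 10))
  expect_equal(m$sensitivity, 40 / 50)
  expect_equal(m$specificity, 30 / 50)
  expect_equal(m$precision, 40 / 60)
  expect_equal(m$accuracy, 70 / 100)
  expect_equal(m$f1, 2 * (2 / 3) * 0.8 / (2 / 3 + 0.8))
  # forced arithmetic: TP = FN, FP = TN = 0
  m2 <- class_metrics(confusion_counts(tp = 5, tn = 0, fp = 0, fn = 5))
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$precision, 1.0)
  expect_true("specificity" %in% m2$undefined)  # TN+FP = 0 -> flagged 0
  expect_error(confusion_counts(0, 0, 0, 0), "all-zero")
})

test_that("weighted averages reduce to dot products with normalized weights", {
  expect_equal(weighted_average(c(0.9, 0.9, 0.9), c(1, 1, 1)), 0.9)
  expect_equal(weighted_average(c(0.2, 0.5, 0.7), c(1, 0, 0)), 0.2)
  set.seed(13)
  for (i in 1:10) {
    v <- runif(5); w <- runif(5)
    oracle <- 0
    for (j in 1:5) oracle <- oracle + v[j] * w[j] / sum(w)
    expect_equal(weighted_average(v, w), oracle)
    expect_gte(weighted_average(v, w), min(v))
    expect_lte(weighted_average(v, w), max(v))
  }
  expect_error(weighted_average(1:3, 1:2), "length")
})

test_that("trapezoidal AUC equals the Mann-Whitney pairwise probability", {
  # perfect separation and pure chance
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)
  set.seed(21)
  for (i in 1:20) {
    truth <- c(1, 0, rbinom(28, 1, 0.4))
    scores <- round(runif(30), 2)  # rounding forces ties
    expect_equal(roc_auc(scores, truth)$auc, mw_auc(scores, truth))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "positive and one negative")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(22)
  truth <- rbinom(40, 1, 0.5); truth[1:2] <- c(0, 1)
  scores <- rnorm(40)
  a0 <- roc_auc(scores, truth)$auc
  expect_equal(roc_auc(exp(scores), truth)$auc, a0)
  expect_equal(roc_auc(2 * scores + 7, truth)$auc, a0)
})

test_that("average precision integrates the PR curve over recall", {
  expect_equal(pr_ap(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$ap, 1.0)
  expect_equal(pr_ap(runif(6), rep(1, 6))$ap, 1.0)  # all-positive truth
  set.seed(23)
  for (i in 1:10) {
    truth <- c(1, rbinom(29, 1, 0.3))
    scores <- round(runif(30), 2)
    expect_equal(pr_ap(scores, truth)$ap, sweep_ap(scores, truth))
  }
  expect_error(pr_ap(runif(4), rep(0, 4)), "positive")
})

test_that("F1 never exceeds the arithmetic mean of precision and sensitivity", {
  set.seed(24)
  p <- runif(1000); s <- runif(1000)
  f <- mapply(f1_score, p, s)
  expect_true(all(f <= (p + s) / 2 + 1e-12))
  expect_equal(f1_score(0.7, 0.7), 0.7)  # equality iff P = S
})

test_that("agreement of a series with itself is perfect", {
  a <- c(310, 450, 290, 520, 380, 405)
  rep <- agreement(a, a)
  expect_equal(rep$icc, 1.0)
  expect_equal(rep$bias, 0)
  expect_equal(rep$loa_high - rep$loa_low, 0)
  expect_true("wilcoxon_all_differences_zero" %in% rep$flags)
})

test_that("a constant offset shows up as bias with collapsed limits", {
  a <- c(310, 450, 290, 520, 380, 405)
  rep <- agreement(a, a + 10)
  expect_equal(rep$bias, -10)     # direction a - b
  expect_equal(rep$loa_low, -10)  # sd of differences is zero
  expect_equal(rep$loa_high, -10)
  expect_lt(rep$icc, 1)
  expect_equal(rep$pearson_r, 1)
})

test_that("simulated raters recover the closed-form ICC", {
  # two raters = truth + independent noise; closed-form ICC is
  # var(subject) / (var(subject) + var(noise)) = 400 / 425
  set.seed(0)
  truth <- rnorm(200, 360, 20)
  a <- truth + rnorm(200, 0, 5)
  b <- truth + rnorm(200, 0, 5)
  rep <- agreement(a, b)
  expect_equal(rep$icc, 400 / 425, tolerance = 0.05)
  expect_true(rep$icc_ci[1] < rep$icc && rep$icc < rep$icc_ci[2])
  expect_gt(rep$pearson_r, 0.9)
})

test_that("degenerate agreement inputs are flagged or rejected", {
  expect_error(agreement(1:5, 1:4), "length")
  expect_error(agreement(c(1, 2), c(1, 2)), "at least 3")
  rep <- agreement(c(5, 5, 5, 5), c(4, 6, 5, 5))
  expect_true("pearson_undefined_zero_variance" %in% rep$flags)
  expect_true(is.na(rep$pearson_r))
})

test_that("prediction evaluation mirrors the per-class plus weighted layout", {
  sc <- cached_scenario()
  pred <- sc$sidecar  # predictions identical to truth
  res <- evaluate_predictions(pred, sc$sidecar)
  present <- res$per_class$n > 0
  expect_true(all(res$per_class$f1[present] == 1))
  expect_equal(res$weighted$accuracy, 1)
  # corrupt a quarter of predictions and expect accuracy to drop accordingly
  set.seed(31)
  flip <- sample(nrow(pred), nrow(pred) %/% 4)
  pred$label[flip] <- ifelse(pred$label[flip] == "normal", "instrument",
                             "normal")
  res2 <- evaluate_predictions(pred, sc$sidecar)
  acc <- sum(pred$label == sc$sidecar$label) / nrow(pred)
  expect_lt(res2$weighted$f1, 1)
  expect_gte(res2$weighted$sensitivity, 0)
})
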