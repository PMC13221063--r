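test_that("confusion battery reproduces the 12-site published outcome", {
  cm <- confusion_metrics(tp = 4, fp = 0, tn = 6, fn = 2)
  expect_equal(cm$sensitivity, 2 / 3)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$accuracy, 10 / 12)
  expect_equal(cm$precision, 1)
  expect_equal(cm$f1, 0.8)
  expect_equal(cm$tss, 2 / 3)
  # predicted prevalence 4/12 vs observed 6/12 deviates by ~16.7 points
  expect_true(cm$prevalence_mismatch)
})

test_that("degenerate counts yield undefined markers with reasons", {
  cm <- confusion_metrics(tp = 10, fp = 0, tn = 0, fn = 0)
  expect_equal(cm$sensitivity, 1)
  expect_true(is.na(cm$specificity))
  expect_match(cm$undefined[["specificity"]], "zero denominator")
  expect_error(confusion_metrics(0, 0, 0, 0), "N = 0")
  expect_error(confusion_metrics(-1, 0, 1, 0), "nonnegative")
  perfect <- confusion_metrics(tp = 5, fp = 0, tn = 7, fn = 0)
  expect_equal(perfect$tss, 1)
})

test_that("TSS and balanced-accuracy identities hold over random counts (property)", {
  set.seed(12)
  for (i in 1:100) {
    k <- as.integer(rmultinom(1, 200, runif(4, 0.05, 1)))
    if (k[1] + k[4] == 0 || k[2] + k[3] == 0) next
    cm <- confusion_metrics(tp = k[1], fp = k[2], tn = k[3], fn = k[4])
    expect_equal(cm$tss, cm$sensitivity + cm$specificity - 1)
    expect_equal(cm$balanced_accuracy, (cm$sensitivity + cm$specificity) / 2)
    expect_equal(cm$balanced_accuracy, (cm$tss + 1) / 2)
    expect_true(cm$tss >= -1 && cm$tss <= 1)
    # prevalence flag iff deviation exceeds 10 percentage points
    # (|pred - obs| = |fp - fn|/N; exact integer comparison)
    expect_identical(cm$prevalence_mismatch,
                     10L * abs(k[2] - k[4]) > sum(k))
  }
})

test_that("rank-based AUC agrees with the pair-counting oracle", {
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1.0)
  expect_equal(auc(c(0.3, 0.5), c(0.3, 0.5)), 0.5)
  expect_equal(auc(c(0.8, 0.6), c(0.7, 0.1)), 0.75)
  set.seed(5)
  for (i in 1:25) {
    p <- round(runif(sample(2:50, 1)), 2)  # rounding forces ties
    b <- round(runif(sample(2:50, 1)), 2)
    expect_equal(auc(p, b), auc_oracle(p, b))
  }
})

test_that("rank-based AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  p <- runif(40, 0.3, 1); b <- runif(60, 0, 0.7)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(p, b),
    quiet = TRUE, direction = "<")))
  expect_equal(auc(p, b), ref)
})

test_that("threshold selection scans candidate cuts correctly", {
  expect_equal(select_threshold(runif(5), runif(5), "default")$threshold, 0.5)
  # perfectly separated sets: both criteria land between the supports
  p <- c(0.8, 0.9); b <- c(0.1, 0.2)
  t1 <- select_threshold(p, b, "MaxSS"); t2 <- select_threshold(p, b, "MinROCdist")
  expect_equal(t1$threshold, t2$threshold)
  expect_gt(t1$threshold, 0.2); expect_lte(t1$threshold, 0.8)
  expect_equal(t1$objective, 2)

  # exhaustive brute-force scan over all candidate cuts: the chosen cut
  # attains the global optimum (here two plateaus tie at sens+spec = 5/3;
  # the tie rule picks the lower one)
  p <- c(0.9, 0.8, 0.4); b <- c(0.5, 0.3, 0.2)
  ch <- select_threshold(p, b, "MaxSS")
  cand <- seq(0, 1, by = 0.001)
  best <- max(vapply(cand, function(t) mean(p >= t) + mean(b < t), 1))
  expect_equal(ch$objective, best)
  expect_equal(mean(p >= ch$threshold) + mean(b < ch$threshold), best)
  expect_equal(ch$threshold, 0.35)
})

test_that("calibration ratio follows its closed form", {
  expect_equal(calibration_ratio(c(0.4, 0.6), c(0.5, 0.5)), 0)
  expect_equal(calibration_ratio(c(0.9, 0.9), c(0.3, 0.3)), 0.5)  # q = 3
  expect_equal(calibration_ratio(c(0, 0), c(0.5, 0.5)), -1)
  expect_error(calibration_ratio(c(0.5), c(0, 0)), "positive")
})

test_that("Boyce index tracks the presence concentration gradient", {
  set.seed(21)
  b <- runif(10000)
  p_good <- rbeta(5000, 4, 1)   # presences concentrated at high suitability
  expect_equal(boyce_index(p_good, b)$boyce, 1.0)
  p_bad <- rbeta(5000, 1, 4)    # reversed: concentrated at low scores
  expect_lt(boyce_index(p_bad, b)$boyce, 0)
  # exchangeable null: the Spearman over 10 windows is noisy for any single
  # draw, but its average over seeded replicates is near zero
  null_vals <- vapply(1:25, function(s) {
    set.seed(s)
    boyce_index(runif(10000), runif(10000))$boyce
  }, numeric(1))
  expect_lt(abs(mean(null_vals)), 0.2)
})

test_that("LOOCV of the HSI is deterministic and self-consistent", {
  sites <- make_sites(n = 12, seed = 5)
  r1 <- loocv_hsi(sites)
  r2 <- loocv_hsi(sites)
  expect_identical(r1, r2)
  expect_gte(r1$rmse, r1$mae)
  expect_equal(mean(r1$table$residual), r1$mean_residual)
  expect_equal(r1$table$residual, r1$table$observed - r1$table$predicted)
  expect_length(r1$failed, 0)
  expect_lte(r1$r_squared, 1)
  expect_error(loocv_hsi(sites[1:2, ]), "at least 3")
})
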