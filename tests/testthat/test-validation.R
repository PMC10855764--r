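test_that("confusion counts enumerate the four outcomes", {
  cc <- confusion(rep(c("p", "n"), each = 10), rep(c("p", "n"), each = 10), "p")
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 10, tn = 10, fp = 0, fn = 0))
  cc2 <- confusion(rep(c("p", "n"), each = 10), rep("p", 20), "p")
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]),
               c(tp = 10, tn = 0, fp = 10, fn = 0))
  cc3 <- confusion(c("p", "p", "n", "n"), c("p", "n", "n", "p"), "p")
  expect_equal(unlist(cc3[c("tp", "tn", "fp", "fn")]),
               c(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_error(confusion(c("p", "n"), "p", "p"), "length")
  expect_error(confusion(c("a", "b"), c("a", "b"), "zz"), "absent")
})

test_that("efficiency reproduces its printed worked examples", {
  expect_equal(round(efficiency(0.990, 0.818), 3), 0.900)
  expect_equal(efficiency(1, 1), 1)
  expect_equal(round(efficiency(0.467, 1.000), 3), 0.683)
})

test_that("precision and Matthews handle degenerate margins as missing", {
  expect_equal(precision(voccheese:::confusion_counts(45, 0, 0, 0)), 1)
  expect_equal(precision(voccheese:::confusion_counts(40, 0, 10, 0)), 0.8)
  expect_true(is.na(precision(voccheese:::confusion_counts(0, 5, 0, 3))))

  expect_equal(matthews(voccheese:::confusion_counts(10, 10, 0, 0)), 1)
  expect_equal(matthews(voccheese:::confusion_counts(5, 5, 5, 5)), 0)
  expect_equal(matthews(voccheese:::confusion_counts(40, 40, 5, 5)),
               1575 / 2025)
  expect_true(is.na(matthews(voccheese:::confusion_counts(0, 10, 0, 0))))
})

test_that("accuracy, sensitivity and specificity come from their ratios", {
  m <- classification_metrics(voccheese:::confusion_counts(10, 10, 0, 0))
  expect_equal(m, c(accuracy = 1, sensitivity = 1, specificity = 1))
  m2 <- classification_metrics(voccheese:::confusion_counts(9, 8, 2, 1))
  expect_equal(m2, c(accuracy = 0.85, sensitivity = 0.9, specificity = 0.8))
  m3 <- classification_metrics(voccheese:::confusion_counts(0, 8, 0, 0))
  expect_true(is.na(m3["sensitivity"]))
})

test_that("metric formulas agree with brute-force arithmetic over all small matrices", {
  for (tp in 0:6) for (tn in 0:6) for (fp in 0:6) for (fn in 0:6) {
    if (tp + tn + fp + fn == 0) next
    cc <- voccheese:::confusion_counts(tp, tn, fp, fn)
    m <- classification_metrics(cc)
    expect_equal(m[["accuracy"]], (tp + tn) / (tp + tn + fp + fn),
                 tolerance = 1e-12)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    expect_identical(is.na(m[["sensitivity"]]), is.na(sens))
    if (!is.na(sens)) expect_equal(m[["sensitivity"]], sens, tolerance = 1e-12)
    if (!is.na(spec)) expect_equal(m[["specificity"]], spec, tolerance = 1e-12)
    if (!is.na(sens) && !is.na(spec)) {
      expect_equal(efficiency(sens, spec), sqrt(sens * spec), tolerance = 1e-12)
    }
    p <- precision(cc)
    if (tp + fp > 0) expect_equal(p, tp / (tp + fp), tolerance = 1e-12)
    else expect_true(is.na(p))
    mc <- matthews(cc)
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    if (denom > 0) {
      expect_equal(mc, (tp * tn - fp * fn) / denom, tolerance = 1e-12)
      expect_true(mc >= -1 - 1e-12 && mc <= 1 + 1e-12)
    } else {
      expect_true(is.na(mc))
    }
  }
})

test_that("cross-validated regression metrics follow their definitions", {
  y <- c(1, 1, 0, 0)
  expect_equal(regression_cv_metrics(y, y),
               c(rmsecv = 0, q2 = 1, dq2 = 1))
  expect_equal(regression_cv_metrics(y, rep(mean(y), 4))[["q2"]], 0)
  # overshoot beyond the label is zeroed by DQ2 only
  yhat <- c(1.4, 0.9, 0.1, -0.3)
  m <- regression_cv_metrics(y, yhat)
  press_q2 <- sum((y - yhat)^2)
  press_dq2 <- sum(c(0, 0.1, 0.1, 0)^2)
  tss <- sum((y - 0.5)^2)
  expect_equal(m[["q2"]], 1 - press_q2 / tss)
  expect_equal(m[["dq2"]], 1 - press_dq2 / tss)
  expect_gte(m[["dq2"]], m[["q2"]])
  expect_true(is.na(regression_cv_metrics(c(1, 1), c(1, 0.5))[["q2"]]))
})

test_that("DQ2 is never below Q2 on random prediction vectors", {
  withr::with_seed(90, {
    for (i in 1:50) {
      n <- sample(6:30, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      yhat <- rnorm(n, y, 0.8)
      m <- regression_cv_metrics(y, yhat)
      expect_gte(m[["dq2"]], m[["q2"]])
    }
  })
})

test_that("AUROC equals exhaustive pair counting", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.85, 0.1)), 0.75)
  expect_equal(auroc(c(1, 1, 0, 0), c(2, 3, 0, 1)), 1)
  expect_equal(auroc(c(1, 0), c(0.5, 0.5)), 0.5)  # tie counted one half
  withr::with_seed(91, {
    for (i in 1:30) {
      n <- sample(4:12, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))  # both classes present
      s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forces ties
      expect_equal(auroc(y, s), pairwise_auroc(y, s), tolerance = 1e-12)
    }
  })
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "one class absent")
})

test_that("binomial reference is the exact null for misclassification counts", {
  ref <- binomial_reference(90, 0.5)
  expect_equal(ref$mean, 45)
  expect_equal(sum(ref$pmf), 1, tolerance = 1e-12)
  expect_equal(binomial_reference(1)$pmf, c(0.5, 0.5))
})

test_that("double cross-validation is deterministic and stratified", {
  cl <- separable_clouds(n = 15, gap = 8, seed = 2)
  a <- double_cross_validate(cl$X, cl$labels, n_repetitions = 2, seed = 5)
  b <- double_cross_validate(cl$X, cl$labels, n_repetitions = 2, seed = 5)
  expect_identical(a, b)
  expect_error(double_cross_validate(cl$X, cl$labels, outer_k = 20,
                                     n_repetitions = 1, seed = 1),
               "fewer than")
})

test_that("double cross-validation scores separable data near-perfectly", {
  cl <- separable_clouds(n = 15, gap = 8, seed = 3)
  cv <- double_cross_validate(cl$X, cl$labels, n_repetitions = 3, seed = 5)
  expect_gte(min(cv$mean["accuracy", ]), 0.95)
  expect_gte(min(cv$mean["auroc", ]), 0.99)
  expect_equal(mean(cv$overall_accuracy), 1, tolerance = 0.05)
})

test_that("uninformative predictors yield chance-level accuracy and Q2 <= 0", {
  withr::with_seed(94, X <- matrix(rnorm(60 * 10), 60, 10))
  labels <- rep(c("a", "b"), each = 30)
  cv <- double_cross_validate(X, labels, n_repetitions = 5, seed = 6)
  expect_equal(mean(cv$overall_accuracy), 0.5, tolerance = 0.15)
  expect_true(all(cv$mean["q2", ] <= 0.05))
  # an informative copy of the labels drives accuracy to 1 (signal sanity)
  X2 <- cbind(X, sig = as.numeric(labels == "a"))
  cv2 <- double_cross_validate(X2, labels, n_repetitions = 2, seed = 6)
  expect_equal(mean(cv2$overall_accuracy), 1)
})

test_that("report table mirrors the mean/median panel layout", {
  cl <- separable_clouds(n = 15, gap = 8, seed = 4)
  cv <- double_cross_validate(cl$X, cl$labels, n_repetitions = 3, seed = 5)
  tab <- cv_report_table(cv)
  expect_equal(tab$metric,
               c("rmsecv", "q2", "dq2", "accuracy", "sensitivity",
                 "specificity", "efficiency", "precision", "matthews", "auroc"))
  expect_equal(setdiff(names(tab), "metric"),
               c("neg_mean", "neg_median", "pos_mean", "pos_median"))
  # median columns are order statistics of the per-repetition values
  expect_equal(tab[tab$metric == "accuracy", "pos_median"],
               stats::median(cv$per_repetition["accuracy", "pos", ]))
})

test_that("permutation test finds separable data significant", {
  cl <- separable_clouds(n = 10, gap = 8, seed = 7)
  pt <- permutation_test(cl$X, cl$labels, n_iterations = 30, max_lv = 2,
                         seed = 8)
  expect_equal(pt$observed, 0)
  expect_equal(pt$p_value, 1 / 31)
  expect_true(all(pt$misclassified >= 0 & pt$misclassified <= pt$n_samples))
  expect_equal(pt$reference$mean, pt$n_samples / 2)
})

test_that("permutation null has binomial-like center on null data", {
  withr::with_seed(95, X <- matrix(rnorm(40 * 8), 40, 8))
  labels <- rep(c("a", "b"), each = 20)
  pt <- permutation_test(X, labels, n_iterations = 60, max_lv = 2, seed = 9)
  expect_equal(mean(pt$misclassified) / 40, 0.5, tolerance = 0.08)
  # two seeds give distributions the KS test cannot tell apart
  pt2 <- permutation_test(X, labels, n_iterations = 60, max_lv = 2, seed = 10)
  ks <- suppressWarnings(stats::ks.test(pt$misclassified, pt2$misclassified))
  expect_gt(ks$p.value, 0.01)
})
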