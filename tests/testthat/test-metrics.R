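# Threshold-independent and threshold-dependent accuracy measures.

test_that("reliability metrics match hand-computed values", {
  perfect <- numeric_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mxe, 0, tolerance = 1e-12)

  # the constant-prevalence predictor is forced to R2 = 0 by the formula
  flat <- numeric_metrics(c(0.5, 0.5), c(1, 0))
  expect_equal(flat$rmse, 0.5, tolerance = 1e-10)
  expect_equal(flat$mae, 0.5, tolerance = 1e-10)
  expect_equal(flat$r2, 0, tolerance = 1e-10)
  expect_equal(flat$mxe, log(2), tolerance = 1e-10)

  m <- numeric_metrics(c(0.9, 0.2), c(1, 0))
  expect_equal(m$rmse, sqrt(0.025), tolerance = 1e-10)
  expect_equal(m$mae, 0.15, tolerance = 1e-10)
  expect_equal(m$r2, 0.9, tolerance = 1e-10)
  expect_equal(m$mxe, -(log(0.9) + log(0.8)) / 2, tolerance = 1e-10)

  # extreme vote proportions are clamped, not infinite
  expect_true(is.finite(numeric_metrics(c(1, 0), c(0, 1))$mxe))
  # single-class samples flag R2 as undefined rather than crash
  expect_true(is.na(numeric_metrics(c(0.4, 0.6), c(1, 1))$r2))
  expect_error(numeric_metrics(c(0.5, 1.2), c(1, 0)), "\\[0, 1\\]")
})

test_that("ROC AUC follows the Mann-Whitney form with half ties", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auc_roc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
})

test_that("the R2 identity and the threshold-sweep AUC oracle hold on random samples", {
  set.seed(99)
  for (i in 1:100) {
    s <- random_sample(sample(10:60, 1))
    q <- mean(s$o)
    m <- numeric_metrics(s$p, s$o)
    expect_equal(m$r2, 1 - m$rmse^2 / (q * (1 - q)), tolerance = 1e-10)
    expect_equal(auc_roc(s$p, s$o), roc_auc_sweep(s$p, s$o), tolerance = 1e-10)
  }
})

test_that("the sensitivity curve is monotone non-increasing in the threshold", {
  set.seed(4)
  for (i in 1:20) {
    s <- random_sample(40)
    sw <- threshold_sweep(s$p, s$o)
    expect_true(all(diff(sw$sensitivity) <= 1e-12))
    expect_true(all(diff(sw$specificity) >= -1e-12))
    expect_true(all(sw$TP + sw$FP + sw$TN + sw$FN == length(s$p)))
  }
})

test_that("auc_suite integrates the three curves over the candidate grid", {
  s <- list(p = c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1), o = c(1, 1, 1, 0, 0, 0))
  a <- auc_suite(s$p, s$o)
  expect_equal(a$auc_roc, 1)
  sw <- threshold_sweep(s$p, s$o)
  tz <- function(y) sum(diff(sw$threshold) * (y[-1] + y[-length(y)]) / 2)
  expect_equal(a$auc_sens, tz(sw$sensitivity), tolerance = 1e-12)
  expect_equal(a$auc_spec, tz(sw$specificity), tolerance = 1e-12)
  expect_equal(a$auc_acc, tz(sw$oa), tolerance = 1e-12)
  # one-class samples flag all AUCs undefined
  expect_true(all(is.na(unlist(auc_suite(c(0.2, 0.4), c(1, 1))))))
})

test_that("confusion counts and the derived measures match hand tallies", {
  cm <- confusion(c(0.9, 0.7, 0.4, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(cm, list(TP = 2L, FP = 0L, TN = 2L, FN = 0L),
    ignore_attr = TRUE)
  # threshold 0 predicts everything present; above max(p), nothing
  cm0 <- confusion(c(0.9, 0.7, 0.4, 0.2), c(1, 1, 0, 0), 0)
  expect_equal(cm0$FN + cm0$TN, 0)
  cm1 <- confusion(c(0.9, 0.7, 0.4, 0.2), c(1, 1, 0, 0), 0.95)
  expect_equal(cm1$TP + cm1$FP, 0)

  perfect <- confusion_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(
    sensitivity = 1, specificity = 1, oa = 1, kappa = 1, tss = 1
  ))
  # hand-computed balanced case: p_e = 0.5
  m <- confusion_metrics(list(TP = 40, FN = 10, TN = 40, FP = 10))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$oa, 0.8)
  expect_equal(m$tss, 0.6, tolerance = 1e-12)
  expect_equal(m$kappa, 0.6, tolerance = 1e-12)
  # TSS is exactly sens + spec - 1
  m2 <- confusion_metrics(list(TP = 8, FN = 2, TN = 7, FP = 3))
  expect_equal(m2$tss, m2$sensitivity + m2$specificity - 1)
  # degenerate single-cell matrix: kappa undefined
  expect_true(is.na(confusion_metrics(list(TP = 5, FP = 0, TN = 0, FN = 0))$kappa))
})

test_that("kappa equals TSS in the exactly balanced case TP = TN, FP = FN", {
  set.seed(10)
  for (i in 1:20) {
    tp <- sample(1:30, 1)
    fp <- sample(0:30, 1)
    m <- confusion_metrics(list(TP = tp, TN = tp, FP = fp, FN = fp))
    expect_equal(m$kappa, m$tss, tolerance = 1e-12)
  }
})
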