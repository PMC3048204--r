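toy_scores <- c(100, 200, 300, 10, 20, 400)
toy_labels <- c(rep("malignant", 3), rep("benign", 3))

test_that("confusion counting at a fixed cutoff is exact", {
  cm <- confusion_at_cutoff(toy_scores, toy_labels, 50)
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = 3, fp = 1, tn = 2, fn = 0))
  cm_hi <- confusion_at_cutoff(toy_scores, toy_labels, 500)
  expect_equal(cm_hi$tp + cm_hi$fp, 0)
  expect_equal(cm_hi$tn + cm_hi$fn, 6)
  expect_error(confusion_at_cutoff(1:3, rep("benign", 3), 2), "malignant")

  # random instance vs exhaustive per-subject check
  set.seed(4)
  inst <- random_instance(13, 17, ties = TRUE)
  for (ct in sample(inst$scores, 5)) {
    cm <- confusion_at_cutoff(inst$scores, inst$labels, ct)
    manual <- table(call = inst$scores >= ct, truth = inst$labels)
    expect_equal(cm$tp, sum(inst$scores >= ct & inst$labels == "malignant"))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 30)
  }
})

test_that("sensitivity/specificity agree with the confusion matrix", {
  ss <- sensitivity_specificity_at(toy_scores, toy_labels, 50)
  expect_equal(unname(ss[1]), 100)
  expect_equal(unname(ss[2]), 200 / 3, tolerance = 1e-12)
  expect_equal(unname(sensitivity_specificity_at(toy_scores, toy_labels, 5)),
               c(100, 0))
  set.seed(5)
  inst <- random_instance(10, 12)
  ct <- median(inst$scores)
  cm <- confusion_at_cutoff(inst$scores, inst$labels, ct)
  expect_equal(unname(sensitivity_specificity_at(inst$scores, inst$labels, ct)),
               c(100 * cm$tp / (cm$tp + cm$fn), 100 * cm$tn / (cm$tn + cm$fp)))
})

test_that("Mann-Whitney AUC handles separation, ties and the toy pair count", {
  expect_equal(auc_mann_whitney(c(3, 4, 1, 2), c("malignant", "malignant",
                                                 "benign", "benign"))$auc, 1)
  expect_equal(auc_mann_whitney(rep(7, 6), toy_labels)$auc, 0.5)
  expect_equal(auc_mann_whitney(c(2, 3, 1, 2),
                                c("malignant", "malignant", "benign", "benign"))$auc,
               3.5 / 4)
})

test_that("rank-based AUC equals brute-force pair counting and the ROC trapezoid", {
  set.seed(42)
  for (rep in 1:50) {
    inst <- random_instance(sample(3:25, 1), sample(3:25, 1),
                            ties = rep %% 2 == 0)
    a <- auc_mann_whitney(inst$scores, inst$labels)$auc
    expect_equal(a, brute_auc_pairs(inst$scores, inst$labels), tolerance = 1e-12)
    roc <- roc_curve(inst$scores, inst$labels)
    trap <- sum(diff(roc$one_minus_spec) *
                  (roc$sens[-1] + roc$sens[-nrow(roc)]) / 2)
    expect_equal(a, trap, tolerance = 1e-12)
  }
})

test_that("AUC is label-swap antisymmetric and invariant to monotone transforms", {
  set.seed(8)
  inst <- random_instance(20, 30, ties = TRUE)
  a <- auc_mann_whitney(inst$scores, inst$labels)$auc
  swapped <- ifelse(inst$labels == "benign", "malignant", "benign")
  expect_equal(auc_mann_whitney(inst$scores, swapped)$auc, 1 - a)
  shifted <- exp(inst$scores / 3) + 5
  expect_equal(auc_mann_whitney(shifted, inst$labels)$auc, a)
})

test_that("ROC curve endpoints are (0,0) and (1,1) with monotone coordinates", {
  set.seed(13)
  inst <- random_instance(15, 20, ties = TRUE)
  roc <- roc_curve(inst$scores, inst$labels)
  expect_equal(c(roc$sens[1], roc$one_minus_spec[1]), c(0, 0))
  expect_equal(c(roc$sens[nrow(roc)], roc$one_minus_spec[nrow(roc)]), c(1, 1))
  expect_true(all(diff(roc$sens) >= 0))
  expect_true(all(diff(roc$one_minus_spec) >= 0))
})

test_that("DeLong confidence interval matches pROC and mirrors under label swap", {
  skip_if_not_installed("pROC")
  set.seed(99)
  inst <- random_instance(40, 60)
  est <- auc_confidence_interval(inst$scores, inst$labels)
  ref <- pROC::ci.auc(pROC::roc(inst$labels, inst$scores, levels = c("benign", "malignant"),
                                direction = "<", quiet = TRUE), method = "delong")
  expect_equal(est$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(est$ci_low, as.numeric(ref[1]), tolerance = 1e-10)
  expect_equal(est$ci_high, as.numeric(ref[3]), tolerance = 1e-10)

  swapped <- ifelse(inst$labels == "benign", "malignant", "benign")
  est_sw <- auc_confidence_interval(inst$scores, swapped)
  expect_equal(est_sw$auc, 1 - est$auc)
  expect_equal(est_sw$ci_low, 1 - est$ci_high, tolerance = 1e-12)
  expect_equal(est_sw$ci_high, 1 - est$ci_low, tolerance = 1e-12)
})

test_that("a perfectly separating marker yields a flagged point interval", {
  scores <- c(10, 11, 12, 1, 2, 3)
  est <- auc_confidence_interval(scores, toy_labels)
  expect_equal(c(est$auc, est$ci_low, est$ci_high), c(1, 1, 1))
  expect_true(est$degenerate)
})

test_that("paired AUC comparison is antisymmetric and null on identical scores", {
  set.seed(12)
  inst <- random_instance(25, 35)
  same <- compare_paired_aucs(inst$scores, inst$scores, inst$labels)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  other <- inst$scores + rnorm(60, sd = 0.6)
  ab <- compare_paired_aucs(inst$scores, other, inst$labels)
  ba <- compare_paired_aucs(other, inst$scores, inst$labels)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_true(ab$p >= 0 && ab$p <= 1)
})

test_that("paired DeLong z and p match pROC's correlated-ROC test", {
  skip_if_not_installed("pROC")
  set.seed(31)
  inst <- random_instance(30, 45)
  other <- 0.7 * inst$scores + rnorm(75, sd = 0.8)
  cmp <- compare_paired_aucs(inst$scores, other, inst$labels)
  ra <- pROC::roc(inst$labels, inst$scores, levels = c("benign", "malignant"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(inst$labels, other, levels = c("benign", "malignant"),
                  direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(cmp$z), abs(as.numeric(ref$statistic)), tolerance = 1e-10)
  expect_equal(cmp$p, as.numeric(ref$p.value), tolerance = 1e-10)
})

test_that("best-accuracy cutoff search matches exhaustive brute force", {
  res <- find_ideal_cutoff(toy_scores, toy_labels)
  expect_equal(res$cutoff, 100)
  expect_equal(res$accuracy, 5 / 6)
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 200 / 3, tolerance = 1e-12)

  sep <- find_ideal_cutoff(c(10, 11, 12, 1, 2, 3), toy_labels)
  expect_equal(sep$accuracy, 1)
  expect_equal(sep$cutoff, 10)

  set.seed(77)
  for (rep in 1:200) {
    inst <- random_instance(sample(3:15, 1), sample(3:15, 1), ties = TRUE)
    got <- find_ideal_cutoff(inst$scores, inst$labels)
    want <- brute_ideal_cutoff(inst$scores, inst$labels)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$accuracy, want$acc)
  }
})
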