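test_that("confusion-matrix metrics follow the closed-form definitions", {
  m <- metrics_from_confusion(fx_confusion(10, 8, 2, 0))
  expect_equal(unname(m["f1"]), 20 / 22)
  expect_equal(round(unname(m["f1"]), 2), 0.91)
  expect_equal(unname(m["sensitivity"]), 1.0)
  expect_equal(unname(m["specificity"]), 0.8)

  perfect <- metrics_from_confusion(fx_confusion(5, 5, 0, 0))
  expect_true(all(perfect == 1))

  even <- metrics_from_confusion(fx_confusion(25, 25, 25, 25))
  expect_equal(unname(even["accuracy"]), 0.5)
  expect_equal(unname(even["mcc"]), 0)
  expect_equal(unname(even["f1"]), 0.5)

  # degenerate single-predicted-class matrix: MCC defined as 0
  degen <- metrics_from_confusion(fx_confusion(10, 0, 10, 0))
  expect_equal(unname(degen["mcc"]), 0)

  expect_error(fx_confusion(0, 0, 0, 0), "at least one")
  expect_error(fx_confusion(-1, 2, 0, 0), "nonnegative")
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(5)
  for (i in 1:50) {
    cm <- fx_confusion(sample(0:30, 1), sample(0:30, 1),
                       sample(0:30, 1), sample(0:30, 1))
    if (cm$tp + cm$tn + cm$fp + cm$fn == 0) next
    m <- metrics_from_confusion(cm)
    total <- cm$tp + cm$tn + cm$fp + cm$fn
    # accuracy decomposes into class-conditional rates
    if (!is.nan(m["sensitivity"]) && !is.nan(m["specificity"])) {
      expect_equal(unname(m["accuracy"]),
                   unname((m["sensitivity"] * (cm$tp + cm$fn) +
                           m["specificity"] * (cm$tn + cm$fp)) / total))
    }
    # F1 is the harmonic mean of precision and recall
    if (cm$tp + cm$fp > 0 && cm$tp + cm$fn > 0 && cm$tp > 0) {
      prec <- cm$tp / (cm$tp + cm$fp)
      rec <- cm$tp / (cm$tp + cm$fn)
      expect_equal(unname(m["f1"]), 2 * prec * rec / (prec + rec))
    }
    expect_gte(m["mcc"], -1)
    expect_lte(m["mcc"], 1)
  }
  # MCC = 1 iff no misclassifications with both classes present
  expect_equal(unname(metrics_from_confusion(fx_confusion(7, 3, 0, 0))["mcc"]), 1)
})

test_that("ROC/AUC matches the pairwise rank formulation, ties worth 1/2", {
  r <- roc_auc(c(0.9, 0.7, 0.7, 0.2), c("pos", "pos", "neg", "neg"),
               positive = "pos")
  expect_equal(r$auc, 0.875)

  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), positive = "1")$auc, 1)
  expect_equal(roc_auc(c(10, 11, 1, 2, 3), c(0, 0, 1, 1, 1), positive = "1")$auc, 0)

  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    labels <- c("pos", "neg", sample(c("pos", "neg"), n - 2, replace = TRUE))
    scores <- round(runif(n), 1)  # coarse grid to force ties
    r <- roc_auc(scores, labels, positive = "pos")
    expect_equal(r$auc, auc_pairwise(scores, labels, "pos"))
    # curve endpoints
    expect_equal(r$points$sensitivity[1], 0)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$sensitivity[nrow(r$points)], 1)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
  }
  expect_error(roc_auc(1:3, rep("pos", 3)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:20) {
    labels <- sample(c("pos", "neg"), 30, replace = TRUE, prob = c(.4, .6))
    if (length(unique(labels)) < 2) next
    scores <- rnorm(30) + (labels == "pos")
    ours <- roc_auc(scores, labels, positive = "pos")$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("neg", "pos"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(ours, ref)
  }
})

test_that("mirrored scores mirror the AUC when scores are tie-free", {
  set.seed(31)
  for (i in 1:20) {
    labels <- c("pos", "neg", sample(c("pos", "neg"), 10, replace = TRUE))
    scores <- rnorm(12)
    a1 <- roc_auc(scores, labels, positive = "pos")$auc
    a2 <- roc_auc(-scores, labels, positive = "pos")$auc
    expect_equal(a1 + a2, 1)
  }
})

test_that("screening PPV applies Bayes' rule and behaves monotonically", {
  est <- screening_ppv(0.81, 0.81, 1 / 151)
  expect_equal(est$prevalence_percent, 0.662, tolerance = 1e-3)
  expect_equal(est$ppv_percent, 2.76, tolerance = 2e-3)
  expect_equal(est$ppv,
               0.81 * (1 / 151) / (0.81 * (1 / 151) + 0.19 * (150 / 151)))

  expect_equal(screening_ppv(1, 1, 0.3)$ppv, 1)

  # strictly increasing in prevalence and specificity
  p1 <- screening_ppv(0.8, 0.8, 0.01)$ppv
  p2 <- screening_ppv(0.8, 0.8, 0.02)$ppv
  p3 <- screening_ppv(0.8, 0.9, 0.01)$ppv
  expect_gt(p2, p1)
  expect_gt(p3, p1)

  expect_error(screening_ppv(0.8, 0.8, 0), "prevalence")
  expect_error(screening_ppv(0.8, 0.8, 1), "prevalence")
})

test_that("two-sample t reproduces summary-statistic and raw-vector oracles", {
  # printed summary statistics of the matched-education comparison
  tt <- two_sample_t(summary_stats(3.16, 0.66, 100),
                     summary_stats(3.14, 0.75, 100))
  expect_equal(tt$statistic, 0.2001903, tolerance = 1e-6)
  expect_equal(tt$df, 198)

  # hand-evaluated pooled formula
  expect_equal(two_sample_t(summary_stats(1, 1, 100),
                            summary_stats(0, 1, 100))$statistic,
               7.071, tolerance = 1e-3)

  # identical groups -> t = 0
  expect_equal(two_sample_t(summary_stats(5, 2, 10),
                            summary_stats(5, 2, 10))$statistic, 0)
  expect_equal(two_sample_t(c(1, 1, 1), c(1, 1, 1))$statistic, 0)

  # raw-vector path cross-checked against stats::t.test
  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(12, 1)
    b <- rnorm(15)
    ours_p <- two_sample_t(a, b, pooled = TRUE)
    ref_p <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours_p$statistic, unname(ref_p$statistic))
    expect_equal(ours_p$p.value, ref_p$p.value)
    ours_w <- two_sample_t(a, b, pooled = FALSE)
    ref_w <- t.test(a, b)
    expect_equal(ours_w$statistic, unname(ref_w$statistic))
    expect_equal(ours_w$df, unname(ref_w$parameter))
  }
})
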