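# Native implementations of the evaluation statistics: confusion-matrix
# metrics (sensitivity, specificity, accuracy, MCC, F1), ROC/AUC,
# population-screening PPV, and the two-sample t-test from either raw
# vectors or printed summary statistics.

#' Construct a confusion matrix
#'
#' Either from the four counts, or from truth/prediction vectors via
#' `confusion_from_predictions()`.
#'
#' @param tp,tn,fp,fn nonnegative integer counts (positives = carriers).
#' @return `fx_confusion` list.
#' @export
fx_confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers")
  }
  if (sum(counts) < 1) stop("confusion matrix must contain at least one count")
  structure(as.list(counts), class = "fx_confusion")
}

#' @rdname fx_confusion
#' @param truth,predicted label vectors.
#' @param positive label of the positive (carrier) class; defaults to
#'   `"carrier"` when present, else the last factor level.
#' @export
confusion_from_predictions <- function(truth, predicted, positive = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  positive <- resolve_positive(truth, positive)
  fx_confusion(tp = sum(predicted == positive & truth == positive),
               tn = sum(predicted != positive & truth != positive),
               fp = sum(predicted == positive & truth != positive),
               fn = sum(predicted != positive & truth == positive))
}

resolve_positive <- function(labels, positive = NULL) {
  if (!is.null(positive)) return(positive)
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  if ("carrier" %in% lv) "carrier" else lv[length(lv)]
}

#' @export
print.fx_confusion <- function(x, ...) {
  cat(sprintf("<fx_confusion> TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Exact formulas: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' accuracy `(TP+TN)/N`, Matthews correlation
#' `(TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and
#' `F1 = 2TP/(2TP+FN+FP)`. A zero MCC denominator (a degenerate predicted or
#' true class) yields MCC = 0 by convention; sensitivity/specificity with a
#' zero denominator are returned as `NaN`.
#'
#' @param cm an `fx_confusion` (or a list with `tp`, `tn`, `fp`, `fn`).
#' @return named numeric: `sensitivity`, `specificity`, `accuracy`, `mcc`,
#'   `f1`.
#' @export
#' @examples
#' round(metrics_from_confusion(fx_confusion(10, 8, 2, 0))["f1"], 2)  # 0.91
metrics_from_confusion <- function(cm) {
  if (!inherits(cm, "fx_confusion")) cm <- fx_confusion(cm$tp, cm$tn, cm$fp, cm$fn)
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  total <- tp + tn + fp + fn
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / total,
    mcc = mcc,
    f1 = 2 * tp / (2 * tp + fn + fp))
}

#' ROC curve and area under the curve
#'
#' Builds the ROC curve from all distinct score thresholds (larger score =
#' more carrier-like) and computes the AUC by the trapezoid rule, which
#' equals the pairwise rank formulation with ties counted one half.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param positive positive-class label (see [confusion_from_predictions()]).
#' @return `fx_roc` list: `points` data frame (`threshold`, `fpr`,
#'   `sensitivity`), `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.7, 0.7, 0.2), c("pos", "pos", "neg", "neg"),
#'         positive = "pos")$auc  # 0.875
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  positive <- resolve_positive(labels, positive)
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes to be present")
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) sum(scores[is_pos] >= t) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores[!is_pos] >= t) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = data.frame(threshold = thresholds, fpr = fpr,
                                     sensitivity = tpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "fx_roc")
}

#' @export
print.fx_roc <- function(x, ...) {
  cat(sprintf("<fx_roc> AUC = %.4f (%d positives vs %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @export
plot.fx_roc <- function(x, add = FALSE, col = "steelblue4", lwd = 2, ...) {
  if (!add) {
    plot(x$points$fpr, x$points$sensitivity, type = "l", col = col, lwd = lwd,
         xlab = "False-positive rate (1 - specificity)", ylab = "Sensitivity",
         xlim = c(0, 1), ylim = c(0, 1), ...)
    abline(0, 1, lty = 3, col = "grey50")
  } else {
    lines(x$points$fpr, x$points$sensitivity, col = col, lwd = lwd, ...)
  }
  invisible(x)
}

#' Positive predictive value under population screening
#'
#' Bayes' rule for the probability of true carrier status given a positive
#' screen:
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))`.
#' The enrichment factor `PPV / prevalence` is the factor by which a
#' positive screen concentrates carriers relative to unscreened testing
#' (i.e. the reduction in confirmatory genetic tests per carrier found).
#'
#' @param sensitivity,specificity operating point, each in (0, 1].
#' @param prevalence population carrier prevalence in (0, 1); the published
#'   US female FX premutation prevalence is 1/151.
#' @return `fx_screening` list: `sensitivity`, `specificity`, `prevalence`,
#'   `prevalence_percent`, `ppv`, `ppv_percent`, `enrichment`.
#' @export
#' @examples
#' screening_ppv(0.81, 0.81, 1/151)
screening_ppv <- function(sensitivity, specificity, prevalence) {
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("prevalence must lie strictly between 0 and 1")
  }
  if (!(sensitivity > 0 && sensitivity <= 1) ||
      !(specificity > 0 && specificity <= 1)) {
    stop("sensitivity and specificity must lie in (0, 1]")
  }
  ppv <- sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 prevalence = prevalence,
                 prevalence_percent = 100 * prevalence,
                 ppv = ppv, ppv_percent = 100 * ppv,
                 enrichment = ppv / prevalence),
            class = "fx_screening")
}

#' @export
print.fx_screening <- function(x, ...) {
  cat(sprintf("<fx_screening> PPV = %.3f%% at prevalence %.3f%% (sens %.2f, spec %.2f): %.1f-fold enrichment\n",
              x$ppv_percent, x$prevalence_percent, x$sensitivity,
              x$specificity, x$enrichment))
  invisible(x)
}

#' Summary statistics for a group
#'
#' @param mean,sd,n group mean, standard deviation (`sd >= 0`) and size
#'   (`n >= 2`).
#' @return `fx_sumstats` list.
#' @export
summary_stats <- function(mean, sd, n) {
  stopifnot(sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = n), class = "fx_sumstats")
}

#' Independent two-sample t-test
#'
#' Computes the pooled-variance (Student) or unpooled (Welch) t statistic
#' from either raw numeric vectors or printed summary statistics
#' ([summary_stats()]), as used for group and collection-mode comparisons of
#' matched cohorts. With equal group sizes the two statistics coincide. Two
#' zero-variance groups with equal means give t = 0 by convention.
#'
#' @param a,b raw numeric vectors or `fx_sumstats`.
#' @param pooled use the pooled-variance statistic (default TRUE).
#' @return `fx_ttest` list: `statistic`, `df`, `p.value`, `method`,
#'   `estimate` (the two means).
#' @export
#' @examples
#' two_sample_t(summary_stats(3.16, 0.66, 100),
#'              summary_stats(3.14, 0.75, 100))$statistic  # 0.2002
two_sample_t <- function(a, b, pooled = TRUE) {
  as_stats <- function(x) {
    if (inherits(x, "fx_sumstats")) return(x)
    stopifnot(is.numeric(x), length(x) >= 2)
    summary_stats(mean(x), sd(x), length(x))
  }
  a <- as_stats(a)
  b <- as_stats(b)
  v1 <- a$sd^2
  v2 <- b$sd^2
  diff <- a$mean - b$mean
  if (v1 == 0 && v2 == 0) {
    if (diff == 0) {
      return(structure(list(statistic = 0, df = a$n + b$n - 2, p.value = 1,
                            method = "pooled two-sample t (degenerate)",
                            estimate = c(mean_a = a$mean, mean_b = b$mean)),
                       class = "fx_ttest"))
    }
    stop("zero variance in both groups with unequal means: t is infinite")
  }
  if (pooled) {
    sp2 <- ((a$n - 1) * v1 + (b$n - 1) * v2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
    method <- "pooled two-sample t"
  } else {
    se <- sqrt(v1 / a$n + v2 / b$n)
    df <- (v1 / a$n + v2 / b$n)^2 /
      ((v1 / a$n)^2 / (a$n - 1) + (v2 / b$n)^2 / (b$n - 1))
    method <- "Welch two-sample t"
  }
  t <- diff / se
  structure(list(statistic = t, df = df,
                 p.value = 2 * pt(-abs(t), df),
                 method = method,
                 estimate = c(mean_a = a$mean, mean_b = b$mean)),
            class = "fx_ttest")
}

#' @export
print.fx_ttest <- function(x, ...) {
  cat(sprintf("<fx_ttest> %s: t = %.3f, df = %.1f, p = %.3g\n",
              x$method, x$statistic, x$df, x$p.value))
  invisible(x)
}
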