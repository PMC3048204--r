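# Empirical ROC analysis: confusion matrices, Mann-Whitney AUC, DeLong-type
# variance for confidence intervals and paired comparison, and the
# best-accuracy cutoff search. A subject is called positive iff its score is
# greater than or equal to the cutoff (the same closed bound as the ROMA
# threshold).

.check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  if (!all(labels %in% c("benign", "malignant"))) {
    stop("labels must be 'benign' or 'malignant'")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!any(labels == "malignant")) stop("no malignant (diseased) subjects in input")
  if (!any(labels == "benign")) stop("no benign (non-diseased) subjects in input")
  invisible(TRUE)
}

#' Confusion matrix at a fixed cutoff
#'
#' Counts true/false positives and negatives when subjects with
#' `score >= cutoff` are called positive and the `"malignant"` label is the
#' diseased class.
#'
#' @param scores numeric scores, one per subject.
#' @param labels `"benign"`/`"malignant"` per subject, aligned with `scores`.
#' @param cutoff decision threshold (may be `Inf` for the all-negative rule).
#' @return a list of class `confusion_matrix` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  .check_scores_labels(scores, labels)
  pos <- scores >= cutoff
  dis <- labels == "malignant"
  structure(list(tp = sum(pos & dis), fp = sum(pos & !dis),
                 tn = sum(!pos & !dis), fn = sum(!pos & dis)),
            class = "confusion_matrix")
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' `sensitivity = 100 * tp / (tp + fn)`, `specificity = 100 * tn / (tn + fp)`,
#' both in percent, from [confusion_at_cutoff()].
#'
#' @inheritParams confusion_at_cutoff
#' @return named numeric vector `c(sensitivity, specificity)` in percent.
#' @export
sensitivity_specificity_at <- function(scores, labels, cutoff) {
  cm <- confusion_at_cutoff(scores, labels, cutoff)
  c(sensitivity = 100 * cm$tp / (cm$tp + cm$fn),
    specificity = 100 * cm$tn / (cm$tn + cm$fp))
}

#' Empirical ROC curve
#'
#' Sweeps the cutoff over every distinct observed score (plus an `Inf`
#' sentinel for the all-negative rule) under the `>=` calling convention,
#' so the curve runs from (0, 0) to (1, 1).
#'
#' @inheritParams confusion_at_cutoff
#' @return a data.frame of class `roc_curve` with columns `cutoff`, `sens`,
#'   `one_minus_spec`, ordered from the all-negative to the all-positive rule.
#' @export
roc_curve <- function(scores, labels) {
  .check_scores_labels(scores, labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  dis <- labels == "malignant"
  n1 <- sum(dis); n0 <- sum(!dis)
  sens <- vapply(cuts, function(ct) sum(scores >= ct & dis) / n1, numeric(1))
  fpr  <- vapply(cuts, function(ct) sum(scores >= ct & !dis) / n0, numeric(1))
  structure(data.frame(cutoff = cuts, sens = sens, one_minus_spec = fpr),
            class = c("roc_curve", "data.frame"))
}

# trapezoidal area under an empirical ROC curve
.roc_trapezoid_area <- function(roc) {
  x <- roc$one_minus_spec; y <- roc$sens
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# Placement values (the DeLong components): for each diseased subject the
# fraction of non-diseased it outranks (ties half), and vice versa. Computed
# with the midrank identity in O(n log n).
.placements <- function(scores, dis) {
  x <- scores[dis]; y <- scores[!dis]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- (m - (r_all[m + seq_len(n)] - rank(y, ties.method = "average"))) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

#' Mann-Whitney AUC estimate
#'
#' The area under the empirical ROC curve, computed as the Mann-Whitney
#' probability that a randomly chosen diseased subject outscores a randomly
#' chosen non-diseased subject, with ties counted one half. This equals the
#' trapezoidal area under the empirical ROC exactly.
#'
#' @inheritParams confusion_at_cutoff
#' @return an object of class `auc_estimate` with fields `auc`, `ci_low`,
#'   `ci_high` (equal to `auc` here; see [auc_confidence_interval()]),
#'   `method`, `n_diseased`, `n_nondiseased`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  .check_scores_labels(scores, labels)
  pl <- .placements(scores, labels == "malignant")
  auc <- mean(pl$v10)
  structure(list(auc = auc, ci_low = auc, ci_high = auc,
                 method = "mann-whitney", level = NA_real_, degenerate = FALSE,
                 n_diseased = pl$m, n_nondiseased = pl$n),
            class = "auc_estimate")
}

#' AUC with a DeLong-type confidence interval
#'
#' Nonparametric variance of the Mann-Whitney AUC from the placement-value
#' components (`var(AUC) = S10/n1 + S01/n0`), with a normal-approximation
#' interval clipped to \[0, 1\]. When the empirical variance is exactly zero
#' (perfect or fully reversed separation) the point interval is returned with
#' `degenerate = TRUE` rather than silently widened.
#'
#' @inheritParams confusion_at_cutoff
#' @param level confidence level, default 0.95.
#' @return an object of class `auc_estimate`.
#' @export
auc_confidence_interval <- function(scores, labels, level = 0.95) {
  .check_scores_labels(scores, labels)
  stopifnot(level > 0, level < 1)
  pl <- .placements(scores, labels == "malignant")
  if (pl$m < 2L || pl$n < 2L) {
    stop("need at least 2 subjects per class for a confidence interval")
  }
  auc <- mean(pl$v10)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  degenerate <- v <= 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- if (degenerate) 0 else z * sqrt(v)
  structure(list(auc = auc,
                 ci_low = max(0, auc - half), ci_high = min(1, auc + half),
                 method = "delong-normal", level = level,
                 degenerate = degenerate,
                 n_diseased = pl$m, n_nondiseased = pl$n),
            class = "auc_estimate")
}

#' Paired comparison of two correlated AUCs
#'
#' Tests the equality of the AUCs of two markers measured on the same
#' subjects. The variance of the AUC difference is estimated from the paired
#' placement-value covariance (the DeLong construction for correlated ROC
#' curves); `z = (auc_a - auc_b) / se_delta` is referred to the standard
#' normal for a two-sided p-value.
#'
#' @param scores_a,scores_b scores of the two markers for the same subjects,
#'   in the same order.
#' @param labels `"benign"`/`"malignant"` per subject.
#' @return an object of class `auc_comparison` with fields `auc_a`, `auc_b`,
#'   `delta`, `se_delta`, `z`, `p`, `method`, `degenerate`.
#' @export
compare_paired_aucs <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired comparison requires equal-length score vectors")
  }
  .check_scores_labels(scores_a, labels)
  .check_scores_labels(scores_b, labels)
  dis <- labels == "malignant"
  pa <- .placements(scores_a, dis)
  pb <- .placements(scores_b, dis)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  delta <- auc_a - auc_b
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  degenerate <- FALSE
  if (v <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      z <- sign(delta) * Inf; p <- 0; degenerate <- TRUE
    }
    se <- 0
  } else {
    se <- sqrt(v)
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = delta, se_delta = se,
                 z = z, p = p, method = "delong-paired-placement",
                 degenerate = degenerate),
            class = "auc_comparison")
}

#' Best-accuracy ("ideal") cutoff search
#'
#' Exhaustively evaluates every distinct observed score (plus the `Inf`
#' all-negative sentinel) as a cutoff under the `>=` convention and returns
#' the accuracy maximiser — the threshold with minimal combined false-negative
#' and false-positive count. Ties in accuracy are broken by the higher Youden
#' index (sensitivity + specificity - 1), then by the lower cutoff, so the
#' result is deterministic.
#'
#' @inheritParams confusion_at_cutoff
#' @return an object of class `cutoff_search_result` with fields `cutoff`,
#'   `sensitivity` (%), `specificity` (%), `accuracy` (fraction).
#' @export
find_ideal_cutoff <- function(scores, labels) {
  .check_scores_labels(scores, labels)
  dis <- labels == "malignant"
  n1 <- sum(dis); n0 <- sum(!dis); n <- n1 + n0
  cand <- c(sort(unique(scores)), Inf)
  tp <- vapply(cand, function(ct) sum(scores >= ct & dis), numeric(1))
  fp <- vapply(cand, function(ct) sum(scores >= ct & !dis), numeric(1))
  acc <- (tp + (n0 - fp)) / n
  sens <- tp / n1; spec <- (n0 - fp) / n0
  # lexicographic: max accuracy, then max Youden, then min cutoff; compared on
  # integer numerators (correct count, tp*n0 - fp*n1) so ties are exact
  ord <- order(-(tp + n0 - fp), -(tp * n0 - fp * n1), cand)
  best <- ord[1L]
  structure(list(cutoff = cand[best],
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 accuracy = acc[best]),
            class = "cutoff_search_result")
}

#' @export
print.auc_estimate <- function(x, ...) {
  if (is.na(x$level)) {
    cat(sprintf("AUC = %.3f (%s; n = %d/%d)\n", x$auc, x$method,
                x$n_diseased, x$n_nondiseased))
  } else {
    cat(sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f, %s; n = %d/%d)%s\n",
                x$auc, 100 * x$level, x$ci_low, x$ci_high, x$method,
                x$n_diseased, x$n_nondiseased,
                if (x$degenerate) " [degenerate variance]" else ""))
  }
  invisible(x)
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("paired AUC comparison: %.3f vs %.3f, delta = %+.3f (se %.4f), z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$se_delta, x$z, x$p))
  invisible(x)
}

#' @export
print.cutoff_search_result <- function(x, ...) {
  cat(sprintf("ideal cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%, accuracy %.3f\n",
              x$cutoff, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Plot an empirical ROC curve
#'
#' @param x a `roc_curve` object.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$one_minus_spec, x$sens, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}
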