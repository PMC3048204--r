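# ROMA: predictive index, predicted probability, threshold classification.
#
# The score is a published logistic model with fixed, menopause-specific
# coefficients on the natural-log marker scale:
#   pre-menopausal:  PI = -12.0 + 2.38 ln(HE4) + 0.0626 ln(CA125)
#   post-menopausal: PI = -8.09 + 1.04 ln(HE4) + 0.732  ln(CA125)
#   PP (%) = 100 exp(PI) / (1 + exp(PI))
# The coefficients are validated as published, never re-estimated here.

#' ROMA coefficient sets
#'
#' The menopause-specific intercept and log-marker coefficients of the ROMA
#' predictive index. Defaults are the published values; they are configuration
#' rather than constants so alternative coefficient sets can be swapped in for
#' sensitivity analyses.
#'
#' @param pre,post numeric vectors `c(intercept, he4_coef, ca125_coef)`;
#'   `he4_coef` multiplies `ln(HE4 [pM])` and `ca125_coef` `ln(CA125 [U/ml])`.
#' @return an object of class `roma_coefficients`.
#' @export
roma_coefficients <- function(pre = c(intercept = -12.0, he4_coef = 2.38, ca125_coef = 0.0626),
                              post = c(intercept = -8.09, he4_coef = 1.04, ca125_coef = 0.732)) {
  stopifnot(length(pre) == 3L, length(post) == 3L,
            all(is.finite(pre)), all(is.finite(post)))
  structure(list(pre = unname(pre), post = unname(post)),
            class = "roma_coefficients")
}

#' ROMA risk thresholds
#'
#' Predicted-probability thresholds (percent scale) separating low from high
#' risk of epithelial ovarian cancer. The published defaults are 12.5% for
#' pre-menopausal and 14.4% for post-menopausal women; a predicted probability
#' at or above the threshold is high risk (closed lower bound).
#'
#' @param pre_pct,post_pct thresholds in percent, each in (0, 100).
#' @return an object of class `roma_thresholds`.
#' @export
roma_thresholds <- function(pre_pct = 12.5, post_pct = 14.4) {
  stopifnot(pre_pct > 0, pre_pct < 100, post_pct > 0, post_pct < 100)
  structure(list(pre_pct = pre_pct, post_pct = post_pct),
            class = "roma_thresholds")
}

#' Single-marker reference cutoffs
#'
#' Conventional upper reference limits for the serum markers: 35 U/ml for
#' CA125 and, for HE4, either 70 pM (literature-suggested) or 150 pM (assay
#' product insert).
#'
#' @param ca125_u_ml,he4_pm_moore,he4_pm_insert positive cutoffs.
#' @return an object of class `marker_cutoffs`.
#' @export
marker_cutoffs <- function(ca125_u_ml = 35.0, he4_pm_moore = 70.0, he4_pm_insert = 150.0) {
  stopifnot(ca125_u_ml > 0, he4_pm_moore > 0, he4_pm_insert > 0)
  structure(list(ca125_u_ml = ca125_u_ml, he4_pm_moore = he4_pm_moore,
                 he4_pm_insert = he4_pm_insert),
            class = "marker_cutoffs")
}

#' ROMA predictive index (log-odds)
#'
#' `PI = intercept + he4_coef * ln(he4) + ca125_coef * ln(ca125)` with the
#' coefficient set selected by menopausal status. `ln` is the natural
#' logarithm; markers must be strictly positive. Vectorised over `he4`,
#' `ca125` and `status`.
#'
#' @param he4 serum HE4 in pM (> 0).
#' @param ca125 serum CA125 in U/ml (> 0).
#' @param status `"pre"` or `"post"` (recycled).
#' @param coefs a [roma_coefficients()] object.
#' @return numeric predictive index (dimensionless log-odds).
#' @export
compute_pi <- function(he4, ca125, status, coefs = roma_coefficients()) {
  stopifnot(inherits(coefs, "roma_coefficients"))
  if (any(!is.finite(he4)) || any(he4 <= 0)) {
    stop("compute_pi: he4 must be finite and > 0")
  }
  if (any(!is.finite(ca125)) || any(ca125 <= 0)) {
    stop("compute_pi: ca125 must be finite and > 0")
  }
  if (!all(status %in% c("pre", "post"))) {
    stop("compute_pi: status must be 'pre' or 'post'")
  }
  n <- max(length(he4), length(ca125), length(status))
  he4 <- rep_len(he4, n); ca125 <- rep_len(ca125, n)
  status <- rep_len(status, n)
  cf <- rbind(coefs$pre, coefs$post)[ifelse(status == "pre", 1L, 2L), ,
                                     drop = FALSE]
  cf[, 1L] + cf[, 2L] * log(he4) + cf[, 3L] * log(ca125)
}

#' ROMA predicted probability (percent)
#'
#' The logistic transform of the predictive index on the percent scale,
#' `PP = 100 * exp(PI) / (1 + exp(PI))`, evaluated through the numerically
#' stable logistic so that PP stays strictly inside (0, 100) without overflow
#' for any finite PI.
#'
#' @param pi finite predictive index (log-odds); vectorised.
#' @return predicted probability in percent, in (0, 100).
#' @export
compute_pp <- function(pi) {
  if (any(!is.finite(pi))) stop("compute_pp: pi must be finite")
  100 * stats::plogis(pi)
}

#' Classify a ROMA predicted probability
#'
#' High risk iff PP is greater than or equal to the menopause-specific
#' threshold (12.5% pre, 14.4% post by default); the bound is closed at the
#' threshold.
#'
#' @param pp predicted probability in percent; vectorised.
#' @param status `"pre"` or `"post"` (recycled).
#' @param thresholds a [roma_thresholds()] object.
#' @return character vector, `"low"` or `"high"`.
#' @export
classify_roma <- function(pp, status, thresholds = roma_thresholds()) {
  stopifnot(inherits(thresholds, "roma_thresholds"))
  if (!all(status %in% c("pre", "post"))) {
    stop("classify_roma: status must be 'pre' or 'post'")
  }
  n <- max(length(pp), length(status))
  pp <- rep_len(pp, n); status <- rep_len(status, n)
  thr <- ifelse(status == "pre", thresholds$pre_pct, thresholds$post_pct)
  ifelse(pp >= thr, "high", "low")
}

#' Classify a single marker value against a cutoff
#'
#' Positive iff `value >= cutoff`. The closed lower bound matches the
#' convention used for the ROMA risk threshold, so all classifiers in the
#' package share one boundary rule.
#'
#' @param value marker value(s), > 0.
#' @param cutoff positive cutoff in the same units.
#' @return character vector, `"positive"` or `"negative"`.
#' @export
classify_marker <- function(value, cutoff) {
  stopifnot(all(value > 0), length(cutoff) == 1L, cutoff > 0)
  ifelse(value >= cutoff, "positive", "negative")
}

#' Score every subject in a cohort
#'
#' Vectorised composition of [compute_pi()], [compute_pp()] and
#' [classify_roma()] over a cohort; row order is preserved and the result is
#' element-wise identical to the scalar path.
#'
#' @param cohort a `roma_cohort`.
#' @param coefs a [roma_coefficients()] object.
#' @param thresholds a [roma_thresholds()] object.
#' @return a data.frame with columns `id`, `pi`, `pp_pct`, `roma_class`.
#' @export
score_cohort <- function(cohort, coefs = roma_coefficients(),
                         thresholds = roma_thresholds()) {
  stopifnot(inherits(cohort, "roma_cohort"))
  if (nrow(cohort) == 0L) {
    return(data.frame(id = character(0), pi = numeric(0), pp_pct = numeric(0),
                      roma_class = character(0), stringsAsFactors = FALSE))
  }
  pi <- tryCatch(
    compute_pi(cohort$he4_pm, cohort$ca125_u_ml, cohort$menopausal_status, coefs),
    error = function(e) stop("score_cohort: ", conditionMessage(e)))
  pp <- compute_pp(pi)
  data.frame(id = cohort$id, pi = pi, pp_pct = pp,
             roma_class = classify_roma(pp, cohort$menopausal_status, thresholds),
             stringsAsFactors = FALSE)
}
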