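# Group-comparison statistics for cohort characteristic and marker-level
# tables: median/IQR summaries, Wilcoxon rank-sum, Kruskal-Wallis, Pearson
# chi-square and Student's t. These are thin, contract-enforcing wrappers
# around the standard R tests, normalised to a single result structure.

.test_result <- function(statistic, p, test_name, n_used, flag = NULL) {
  structure(list(statistic = unname(statistic), p = unname(p),
                 test_name = test_name, n_used = n_used, flag = flag),
            class = "roma_test")
}

#' @export
print.roma_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)%s\n", x$test_name,
              x$statistic, x$p, paste(x$n_used, collapse = "/"),
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Median and interquartile range
#'
#' Summarises a sample by its median and quartiles using the
#' linear-interpolation quantile convention (R type 7). Marker-level tables
#' render these to one decimal.
#'
#' @param values non-empty numeric vector.
#' @param group optional group label carried into the result.
#' @return a one-row data.frame with `group`, `n`, `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values, group = NA_character_) {
  if (length(values) == 0L) stop("median_iqr: empty sample")
  if (any(!is.finite(values))) stop("median_iqr: values must be finite")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(group = group, n = length(values),
             median = q[2L], q1 = q[1L], q3 = q[3L],
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided comparison of two independent samples. The exact null
#' distribution is enumerated when the combined sample size is at most 10 and
#' there are no ties (exactness is cheap there); otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @return a `roma_test` result (statistic is the Mann-Whitney U of `x`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("wilcoxon_rank_sum: empty sample")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 10L && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  .test_result(wt$statistic, min(1, wt$p.value),
               if (exact) "wilcoxon-rank-sum (exact)" else "wilcoxon-rank-sum (normal approx.)",
               c(length(x), length(y)))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic across two or more groups with a chi-square
#' reference distribution on k - 1 degrees of freedom. The degenerate case of
#' all observations equal (tie correction removes all variance) is reported
#' as H = 0, p = 1.
#'
#' @param groups a list of two or more non-empty numeric samples.
#' @return a `roma_test` result.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis: need a list of >= 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("kruskal_wallis: empty group")
  }
  ns <- vapply(groups, length, integer(1))
  if (length(unique(unlist(groups))) == 1L) {
    return(.test_result(0, 1, "kruskal-wallis", ns, flag = "all values equal"))
  }
  kt <- stats::kruskal.test(groups)
  .test_result(kt$statistic, kt$p.value, "kruskal-wallis", ns)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction by default, with
#' `df = (r - 1)(k - 1)`; a Yates-corrected variant is available for 2x2
#' tables via `correct = TRUE`.
#'
#' @param table matrix of non-negative counts with at least 2 rows and
#'   2 columns and no zero marginal.
#' @param correct apply the continuity correction (2x2 only).
#' @return a `roma_test` result.
#' @export
chi_square_2xk <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("chi_square_2xk: need at least a 2x2 table")
  }
  if (any(table < 0)) stop("chi_square_2xk: negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi_square_2xk: zero row or column marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  .test_result(ct$statistic, ct$p.value,
               if (correct) "pearson-chi-square (Yates)" else "pearson-chi-square",
               sum(table))
}

#' Student's t-test for two independent samples
#'
#' Pooled-variance two-sided t-test by default (the convention for comparing
#' mean ages between diagnosis classes); Welch's unequal-variance variant via
#' `welch = TRUE`. A degenerate zero-variance input returns p = 1 when the
#' means agree and p = 0 (flagged) when they do not.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @param welch use the Welch variant instead of pooled variance.
#' @return a `roma_test` result.
#' @export
students_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("students_t: need n >= 2 per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(.test_result(0, 1, "student-t", c(length(x), length(y)),
                          flag = "zero variance"))
    }
    return(.test_result(sign(mean(x) - mean(y)) * Inf, 0, "student-t",
                        c(length(x), length(y)), flag = "zero variance"))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  .test_result(tt$statistic, tt$p.value,
               if (welch) "welch-t" else "student-t",
               c(length(x), length(y)))
}

#' Student's t-test from summary statistics
#'
#' Pooled-variance two-sided t-test computed from per-group means, standard
#' deviations and sizes, for checking published characteristic tables that
#' report only summaries.
#'
#' @param mean1,sd1,n1 summary of the first group.
#' @param mean2,sd2,n2 summary of the second group.
#' @return a `roma_test` result.
#' @export
students_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  .test_result(t, 2 * stats::pt(-abs(t), df), "student-t (summary)", c(n1, n2))
}
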