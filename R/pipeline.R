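# Study pipeline: one-call reproduction of the analysis tables of a
# pelvic-mass marker validation study — cohort composition with tests,
# per-group marker summaries, and the stratified diagnostic-performance
# table — plus the named case subgroups used in subgroup ROC analysis.

.marker_scores <- function(cohort, marker, scored = NULL) {
  switch(marker,
         CA125 = cohort$ca125_u_ml,
         HE4 = cohort$he4_pm,
         ROMA = {
           if (is.null(scored)) scored <- score_cohort(cohort)
           scored$pp_pct[match(cohort$id, scored$id)]
         },
         stop("unknown marker: ", marker))
}

#' Named case-subgroup filters
#'
#' The library of malignant-case filters used in subgroup ROC analysis:
#' all malignant tumours; epithelial ovarian cancer (EOC); invasive EOC
#' (borderline excluded); each FIGO stage; early (I-II) and advanced (III-IV)
#' stage; borderline and invasive grades; serous, non-serous, mucinous and
#' non-mucinous EOC (mixed subtypes excluded from the serous/mucinous
#' contrasts). Each filter is a pure predicate over the cohort rows; controls
#' are always the full benign class.
#'
#' @return a named list of functions `cohort -> logical`.
#' @export
subgroup_filters <- function() {
  eoc <- function(d) d$histology_group == "eoc"
  list(
    all_malignant = function(d) d$diagnosis == "malignant",
    eoc = eoc,
    invasive_eoc = function(d) eoc(d) & d$grade != "borderline",
    figo_I = function(d) eoc(d) & d$figo_stage == "I",
    figo_II = function(d) eoc(d) & d$figo_stage == "II",
    figo_III = function(d) eoc(d) & d$figo_stage == "III",
    figo_IV = function(d) eoc(d) & d$figo_stage == "IV",
    early_stage = function(d) eoc(d) & d$figo_stage %in% c("I", "II"),
    advanced_stage = function(d) eoc(d) & d$figo_stage %in% c("III", "IV"),
    borderline = function(d) eoc(d) & d$grade == "borderline",
    invasive_grades = function(d) eoc(d) & d$grade %in% c("g1", "g2", "g3"),
    serous = function(d) eoc(d) & !is.na(d$subtype_tag) & d$subtype_tag == "serous",
    non_serous = function(d) eoc(d) & !is.na(d$subtype_tag) &
      !(d$subtype_tag %in% c("serous", "mixed")),
    mucinous = function(d) eoc(d) & !is.na(d$subtype_tag) & d$subtype_tag == "mucinous",
    non_mucinous = function(d) eoc(d) & !is.na(d$subtype_tag) &
      !(d$subtype_tag %in% c("mucinous", "mixed"))
  )
}

#' AUC of a marker on a case subgroup
#'
#' Cases are the malignant subjects passing the filter; controls are all
#' benign subjects. The AUC is the Mann-Whitney estimate with its DeLong-type
#' confidence interval.
#'
#' @param cohort a `roma_cohort` containing both classes.
#' @param filter a filter name from [subgroup_filters()] or a predicate
#'   function `cohort -> logical`.
#' @param marker `"CA125"`, `"HE4"` or `"ROMA"`.
#' @param level confidence level.
#' @return an `auc_estimate`.
#' @export
evaluate_subgroup <- function(cohort, filter, marker = "ROMA", level = 0.95) {
  stopifnot(inherits(cohort, "roma_cohort"))
  filter_name <- "custom"
  if (is.character(filter)) {
    filter_name <- filter
    lib <- subgroup_filters()
    if (!(filter %in% names(lib))) stop("unknown subgroup filter: ", filter)
    filter <- lib[[filter]]
  }
  keep_case <- filter(cohort) & cohort$diagnosis == "malignant"
  if (!any(keep_case)) {
    stop("evaluate_subgroup: filter '", filter_name, "' matches no malignant case")
  }
  sub <- cohort[keep_case | cohort$diagnosis == "benign", , drop = FALSE]
  class(sub) <- c("roma_cohort", "data.frame")
  auc_confidence_interval(.marker_scores(sub, marker), sub$diagnosis, level)
}

.table1_block <- function(cohort) {
  by_class <- split(seq_len(nrow(cohort)), cohort$diagnosis)
  n_b <- length(by_class$benign); n_m <- length(by_class$malignant)
  n <- n_b + n_m
  age_p <- students_t(cohort$age[by_class$benign], cohort$age[by_class$malignant])$p
  comp <- data.frame(
    variable = "n", benign = n_b, malignant = n_m,
    benign_pct = round(100 * n_b / n, 1), malignant_pct = round(100 * n_m / n, 1),
    p = NA_real_, stringsAsFactors = FALSE)
  rows <- list(comp)
  rows[[2]] <- data.frame(
    variable = "age_mean", benign = mean(cohort$age[by_class$benign]),
    malignant = mean(cohort$age[by_class$malignant]),
    benign_pct = NA_real_, malignant_pct = NA_real_, p = age_p,
    stringsAsFactors = FALSE)
  cat_row <- function(variable, flag_b, flag_m) {
    tab <- rbind(c(sum(flag_b, na.rm = TRUE), sum(!flag_b, na.rm = TRUE)),
                 c(sum(flag_m, na.rm = TRUE), sum(!flag_m, na.rm = TRUE)))
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_ else
      chi_square_2xk(tab)$p
    nb <- sum(!is.na(flag_b)); nm <- sum(!is.na(flag_m))
    data.frame(variable = variable,
               benign = sum(flag_b, na.rm = TRUE),
               malignant = sum(flag_m, na.rm = TRUE),
               benign_pct = round(100 * sum(flag_b, na.rm = TRUE) / nb, 1),
               malignant_pct = round(100 * sum(flag_m, na.rm = TRUE) / nm, 1),
               p = p, stringsAsFactors = FALSE)
  }
  rows[[3]] <- cat_row("post_menopausal",
                       cohort$menopausal_status[by_class$benign] == "post",
                       cohort$menopausal_status[by_class$malignant] == "post")
  k <- 4L
  for (fc in c("smoking", "fh_breast", "fh_ovarian", "haemolysis",
               "freeze_delay_gt_4h")) {
    rows[[k]] <- cat_row(fc, cohort[[fc]][by_class$benign] == 1L,
                         cohort[[fc]][by_class$malignant] == 1L)
    k <- k + 1L
  }
  do.call(rbind, rows)
}

.table4_block <- function(cohort, scored) {
  marker_values <- function(rows, marker) {
    sub <- cohort[rows, , drop = FALSE]
    class(sub) <- c("roma_cohort", "data.frame")
    .marker_scores(sub, marker, scored)
  }
  groupings <- list(
    benign_histology = which(cohort$diagnosis == "benign"),
    malignant_histology = which(cohort$diagnosis == "malignant"))
  rows <- list()
  add_row <- function(section, label, idx) {
    for (mk in c("CA125", "HE4", "ROMA")) {
      s <- median_iqr(marker_values(idx, mk), group = label)
      rows[[length(rows) + 1L]] <<- data.frame(
        section = section, group = label, marker = mk, n = s$n,
        median = s$median, q1 = s$q1, q3 = s$q3, stringsAsFactors = FALSE)
    }
  }
  add_row("overall", "benign", groupings$benign_histology)
  add_row("overall", "malignant", groupings$malignant_histology)
  ben <- cohort$diagnosis == "benign"
  for (hg in unique(cohort$histology_group[ben])) {
    add_row("benign_histology", hg, which(ben & cohort$histology_group == hg))
  }
  mal <- cohort$diagnosis == "malignant"
  for (hg in unique(cohort$histology_group[mal])) {
    add_row("malignant_histology", hg, which(mal & cohort$histology_group == hg))
  }
  for (st in intersect(c("I", "II", "III", "IV"), unique(cohort$figo_stage))) {
    add_row("figo_stage", st, which(cohort$figo_stage == st))
  }
  for (gr in intersect(c("borderline", "g1", "g2", "g3"), unique(cohort$grade))) {
    add_row("grade", gr, which(cohort$grade == gr))
  }
  do.call(rbind, rows)
}

.fixed_cutoff_rows <- function(scores, labels, cutoffs) {
  do.call(rbind, lapply(cutoffs, function(ct) {
    ss <- sensitivity_specificity_at(scores, labels, ct)
    data.frame(cutoff = ct, sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]], stringsAsFactors = FALSE)
  }))
}

.stratum_performance <- function(cohort, scored, stratum, thresholds, cutoffs,
                                 level) {
  labels <- cohort$diagnosis
  scores <- list(CA125 = .marker_scores(cohort, "CA125"),
                 HE4 = .marker_scores(cohort, "HE4"),
                 ROMA = .marker_scores(cohort, "ROMA", scored))
  res <- list()
  for (mk in names(scores)) {
    auc <- auc_confidence_interval(scores[[mk]], labels, level)
    ideal <- find_ideal_cutoff(scores[[mk]], labels)
    fixed <- switch(mk,
      CA125 = .fixed_cutoff_rows(scores[[mk]], labels, cutoffs$ca125_u_ml),
      HE4 = .fixed_cutoff_rows(scores[[mk]], labels,
                               c(cutoffs$he4_pm_moore, cutoffs$he4_pm_insert)),
      ROMA = {
        if (stratum == "all") {
          # pooled suggested-cutoff row: each subject classified at its own
          # menopause-specific threshold, then one pooled confusion matrix
          thr <- ifelse(cohort$menopausal_status == "pre",
                        thresholds$pre_pct, thresholds$post_pct)
          pos <- scores[[mk]] >= thr
          dis <- labels == "malignant"
          data.frame(cutoff = NA_real_,
                     sensitivity = 100 * sum(pos & dis) / sum(dis),
                     specificity = 100 * sum(!pos & !dis) / sum(!dis),
                     stringsAsFactors = FALSE)
        } else {
          ct <- if (stratum == "pre") thresholds$pre_pct else thresholds$post_pct
          .fixed_cutoff_rows(scores[[mk]], labels, ct)
        }
      })
    res[[mk]] <- list(stratum = stratum, marker = mk, auc = auc,
                      ideal = ideal, fixed_cutoffs = fixed)
  }
  res$pairwise <- list(
    HE4_vs_CA125 = compare_paired_aucs(scores$HE4, scores$CA125, labels),
    HE4_vs_ROMA = compare_paired_aucs(scores$HE4, scores$ROMA, labels),
    CA125_vs_ROMA = compare_paired_aucs(scores$CA125, scores$ROMA, labels))
  res
}

#' Run the full study analysis on a cohort
#'
#' Produces the complete report bundle of a marker validation analysis:
#'
#' * `table1`: cohort composition (counts, percentages, mean age, covariate
#'   flags) with Student's t / chi-square comparison p-values;
#' * `table4`: median/IQR of CA125, HE4 and ROMA by diagnosis, histology
#'   group, FIGO stage and grade;
#' * `table5`: per stratum (all / pre- / post-menopausal) and per marker
#'   (CA125, HE4, ROMA): AUC with confidence interval, the three pairwise
#'   DeLong comparisons, the best-accuracy cutoff, and sensitivity and
#'   specificity at the fixed reference cutoffs (CA125 35 U/ml; HE4 70 and
#'   150 pM; ROMA 12.5% / 14.4% by menopausal status);
#' * `subgroups`: ROMA AUC for each named case subgroup in
#'   [subgroup_filters()] that is non-empty.
#'
#' For the pooled stratum the ROMA ROC and AUC are computed on the pooled
#' predicted probabilities (one score axis), while the pooled
#' suggested-cutoff row classifies each subject at its own menopause-specific
#' threshold before pooling the confusion matrix. A stratum with only one
#' diagnosis class is omitted with a warning.
#'
#' @param cohort a `roma_cohort` containing both diagnosis classes.
#' @param coefs,thresholds,cutoffs scoring configuration.
#' @param level confidence level for AUC intervals.
#' @return a list of class `roma_report_bundle`.
#' @export
run_full_analysis <- function(cohort, coefs = roma_coefficients(),
                              thresholds = roma_thresholds(),
                              cutoffs = marker_cutoffs(), level = 0.95) {
  stopifnot(inherits(cohort, "roma_cohort"))
  if (length(unique(cohort$diagnosis)) < 2L) {
    stop("run_full_analysis: cohort must contain benign and malignant subjects")
  }
  scored <- score_cohort(cohort, coefs, thresholds)
  strata <- list(all = cohort)
  for (st in c("pre", "post")) {
    sub <- cohort[cohort$menopausal_status == st, , drop = FALSE]
    class(sub) <- c("roma_cohort", "data.frame")
    if (nrow(sub) == 0L || length(unique(sub$diagnosis)) < 2L) {
      warning("stratum '", st, "' missing or single-class; omitted from the performance table")
    } else {
      strata[[st]] <- sub
    }
  }
  table5 <- lapply(names(strata), function(st) {
    .stratum_performance(strata[[st]], scored, st, thresholds, cutoffs, level)
  })
  names(table5) <- names(strata)

  subgroups <- list()
  for (nm in names(subgroup_filters())) {
    subgroups[[nm]] <- tryCatch(evaluate_subgroup(cohort, nm, "ROMA", level),
                                error = function(e) NULL)
  }
  subgroups <- subgroups[!vapply(subgroups, is.null, logical(1))]

  structure(list(table1 = .table1_block(cohort),
                 table4 = .table4_block(cohort, scored),
                 table5 = table5,
                 subgroups = subgroups,
                 n = nrow(cohort)),
            class = "roma_report_bundle")
}

.table5_frame <- function(bundle) {
  rows <- list()
  for (st in names(bundle$table5)) {
    block <- bundle$table5[[st]]
    for (mk in c("CA125", "HE4", "ROMA")) {
      b <- block[[mk]]
      fixed <- b$fixed_cutoffs
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, marker = mk,
        auc = round(b$auc$auc, 3),
        ci_low = round(b$auc$ci_low, 3), ci_high = round(b$auc$ci_high, 3),
        p_he4_vs_ca125 = block$pairwise$HE4_vs_CA125$p,
        p_he4_vs_roma = block$pairwise$HE4_vs_ROMA$p,
        p_ca125_vs_roma = block$pairwise$CA125_vs_ROMA$p,
        ideal_cutoff = b$ideal$cutoff,
        ideal_sensitivity = round(b$ideal$sensitivity, 1),
        ideal_specificity = round(b$ideal$specificity, 1),
        fixed_cutoff = fixed$cutoff[1],
        fixed_sensitivity = round(fixed$sensitivity[1], 1),
        fixed_specificity = round(fixed$specificity[1], 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a report bundle to disk
#'
#' Renders the bundle as plain-text artefacts: `table1.csv`, `table4.csv`
#' and `table5.csv` mirroring the study table layouts (percentages to one
#' decimal, AUCs to three), `subgroup_aucs.csv`, and the complete bundle as
#' `bundle.json`.
#'
#' @param bundle a `roma_report_bundle`.
#' @param out_dir output directory (created if needed).
#' @return character vector of the file paths written.
#' @export
render_reports <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "roma_report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  t4 <- bundle$table4
  for (col in c("median", "q1", "q3")) t4[[col]] <- round(t4[[col]], 1)
  w(bundle$table1, "table1.csv")
  w(t4, "table4.csv")
  w(.table5_frame(bundle), "table5.csv")
  sub <- do.call(rbind, lapply(names(bundle$subgroups), function(nm) {
    a <- bundle$subgroups[[nm]]
    data.frame(subgroup = nm, marker = "ROMA", auc = round(a$auc, 3),
               ci_low = round(a$ci_low, 3), ci_high = round(a$ci_high, 3),
               n_cases = a$n_diseased, stringsAsFactors = FALSE)
  }))
  w(sub, "subgroup_aucs.csv")
  p <- file.path(out_dir, "bundle.json")
  jsonlite::write_json(.bundle_to_list(bundle), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(paths, p)
}

.bundle_to_list <- function(bundle) {
  strip <- function(x) if (is.list(x) && !is.data.frame(x)) lapply(unclass(x), strip) else x
  strip(unclass(bundle))
}

#' @export
print.roma_report_bundle <- function(x, ...) {
  cat(sprintf("<roma_report_bundle> %d subjects; strata: %s; %d subgroup AUCs\n",
              x$n, paste(names(x$table5), collapse = ", "),
              length(x$subgroups)))
  invisible(x)
}
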