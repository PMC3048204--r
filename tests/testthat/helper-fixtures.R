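# Fixture builders and independent oracles shared across the test files.

# a tiny hand-written cohort data.frame (3 subjects) in schema order
tiny_cohort_df <- function() {
  data.frame(
    id = c("P1", "P2", "P3"),
    age = c(44, 61, 52),
    menopausal_status = c("pre", "post", "pre"),
    ca125_u_ml = c(12.5, 640.0, 35.0),
    he4_pm = c(40.2, 310.5, 70.0),
    diagnosis = c("benign", "malignant", "benign"),
    histology_group = c("endometriosis", "eoc", "functional_cyst"),
    figo_stage = c("not_applicable", "III", "not_applicable"),
    grade = c("not_applicable", "g3", "not_applicable"),
    subtype_tag = c(NA, "serous", NA),
    haemolysis = c(0L, 0L, NA),
    freeze_delay_gt_4h = c(0L, 1L, 0L),
    fh_breast = c(0L, 1L, 0L),
    fh_ovarian = c(0L, 0L, 0L),
    smoking = c(1L, 0L, NA),
    stringsAsFactors = FALSE)
}

# a small synthetic cohort drawn from the calibrated default generator
small_cohort <- function(n_benign = 40L, n_malignant = 30L, seed = 11L) {
  cfg <- perturb_config(default_cohort_config(seed = seed),
                        list(n_benign = n_benign, n_malignant = n_malignant))
  generate_cohort(cfg)
}

# random scores/labels instance for ROC property tests
random_instance <- function(n1, n0, ties = FALSE) {
  cases <- rnorm(n1, mean = 1)
  controls <- rnorm(n0)
  if (ties) {
    cases <- round(cases, 1)
    controls <- round(controls, 1)
  }
  list(scores = c(cases, controls),
       labels = c(rep("malignant", n1), rep("benign", n0)))
}

# O(n1*n0) pair-counting AUC, independent of the rank-based implementation
brute_auc_pairs <- function(scores, labels) {
  x <- scores[labels == "malignant"]
  y <- scores[labels == "benign"]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

# exhaustive best-accuracy search driven only by confusion_at_cutoff,
# replicating the documented tie-break (max accuracy, max Youden, min cutoff)
# with exact integer comparisons
brute_ideal_cutoff <- function(scores, labels) {
  cand <- c(sort(unique(scores)), Inf)
  best <- NULL
  for (ct in cand) {
    cm <- confusion_at_cutoff(scores, labels, ct)
    n1 <- cm$tp + cm$fn; n0 <- cm$tn + cm$fp
    correct <- cm$tp + cm$tn               # accuracy numerator
    yj_num <- cm$tp * n0 - cm$fp * n1      # Youden numerator over n1*n0
    if (is.null(best) || correct > best$correct ||
        (correct == best$correct && yj_num > best$yj_num)) {
      best <- list(cutoff = ct, correct = correct, yj_num = yj_num,
                   acc = correct / (n1 + n0))
    }
  }
  best
}

# exact two-sided Mann-Whitney p by enumerating every rank assignment
enum_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n, n1)
  u_all <- apply(subsets, 2, function(ix) sum(seq_len(n)[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
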