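# romadx

Scoring and diagnostic-performance evaluation for the **Risk of Ovarian
Malignancy Algorithm (ROMA)** in R.

Women presenting with a pelvic mass need to be triaged: benign cysts can be
managed locally, but a malignancy should be referred to a gynaecological
oncology centre. ROMA supports that triage by combining two serum tumour
markers — CA125 (U/ml) and HE4 (pM) — with menopausal status into a predicted
probability of epithelial ovarian cancer (EOC). `romadx` is aimed at
biostatisticians and clinical researchers who validate such markers: it
implements the score itself and everything a validation analysis needs around
it (ROC/AUC with confidence intervals, paired comparison of correlated
markers, cutoff optimisation, rank-based group statistics), plus a calibrated
synthetic cohort generator so the full pipeline runs without patient data.

## The model

ROMA is a fixed-coefficient logistic score on the natural-log marker scale,
with menopause-specific coefficients:

    pre-menopausal:   PI = -12.0 + 2.38 · ln(HE4) + 0.0626 · ln(CA125)
    post-menopausal:  PI = -8.09 + 1.04 · ln(HE4) + 0.732  · ln(CA125)

    PP (%) = 100 · exp(PI) / (1 + exp(PI))

A subject is classified *high risk* when PP ≥ 12.5% (pre-menopausal) or
PP ≥ 14.4% (post-menopausal); both bounds are closed. Single markers are
classified against their conventional upper reference limits (CA125
35 U/ml; HE4 70 pM or 150 pM). The coefficients are validated as
published, never re-estimated.

For evaluation, the package provides:

- `auc_mann_whitney()` / `auc_confidence_interval()` — the Mann–Whitney
  AUC (the probability a random case outscores a random control, ties
  counted half; identical to the trapezoidal area under the empirical ROC)
  with a DeLong placement-value variance and normal-approximation CI;
- `compare_paired_aucs()` — the DeLong test for the difference between two
  correlated AUCs measured on the same subjects;
- `find_ideal_cutoff()` — the exhaustive best-accuracy ("minimal
  false-negative plus false-positive") cutoff search with a deterministic
  tie-break;
- `wilcoxon_rank_sum()`, `kruskal_wallis()`, `chi_square_2xk()`,
  `students_t()`, `median_iqr()` — the group-comparison statistics of
  cohort characteristic and marker-level tables;
- `generate_cohort()` / `default_cohort_config()` — a log-normal mixture
  simulator calibrated to the composition and per-group marker medians/IQRs
  of a published 389-patient pelvic-mass validation cohort;
- `run_full_analysis()` / `render_reports()` — one-call reproduction of the
  composition, marker-level and performance tables of such a study.

## Worked example

```r
library(romadx)

cohort <- generate_cohort(default_cohort_config(seed = 42L))
cohort
#> <roma_cohort> 389 subjects (228 benign, 161 malignant)

scores <- score_cohort(cohort)
head(scores, 3)
#>        id        pi     pp_pct roma_class
#> 1 S000001 -5.694442  0.3353331        low
#> 2 S000002 -1.809335 14.0718523        low
#> 3 S000003 -4.054579  1.7047132        low

auc_confidence_interval(scores$pp_pct, cohort$diagnosis)
#> AUC = 0.882 (95% CI 0.840-0.925, delong-normal; n = 161/228)

find_ideal_cutoff(scores$pp_pct, cohort$diagnosis)
#> ideal cutoff 24.09: sensitivity 80.1%, specificity 95.2%, accuracy 0.889

compare_paired_aucs(cohort$he4_pm, cohort$ca125_u_ml, cohort$diagnosis)
#> paired AUC comparison: 0.833 vs 0.896, delta = -0.063 (se 0.0233), z = -2.691, p = 0.007123

evaluate_subgroup(cohort, "invasive_eoc", "ROMA")
#> AUC = 0.935 (95% CI 0.891-0.979, delong-normal; n = 101/228)
```

Read top to bottom: the synthetic cohort reproduces the reference study's
composition (228 benign / 161 malignant). Each subject gets a predictive
index `pi`, a percent-scale probability `pp_pct` and a risk class at its
menopause-specific threshold. On this cohort ROMA separates malignant from
benign disease with AUC 0.882; the best-accuracy ROMA cutoff lands at 24.1%
(close to the ~22% reported for the real cohort); HE4 alone performs worse
than CA125 alone (p ≈ 0.007, paired DeLong); and restricting cases to
invasive EOC — dropping borderline tumours, which carry the lowest marker
levels — raises the AUC to 0.935, mirroring the subgroup behaviour of the
real study.

The full table set (composition tests, median/IQR tables, the stratified
performance table, subgroup AUCs) comes from:

```r
bundle <- run_full_analysis(cohort)
render_reports(bundle, "reports/")
```

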