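---
title: "Methods: ROMA scoring, ROC evaluation and the synthetic pelvic-mass cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROMA scoring, ROC evaluation and the synthetic pelvic-mass cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romadx)
```

## The score

ROMA is a logistic risk score for epithelial ovarian cancer (EOC) in women
with a pelvic mass. Its linear predictor (the *predictive index*, PI) uses
the natural logarithms of the two serum markers, with coefficient sets fixed
by menopausal status:

$$
\mathrm{PI}_{\text{pre}} = -12.0 + 2.38\,\ln(\mathrm{HE4}) + 0.0626\,\ln(\mathrm{CA125}),
\qquad
\mathrm{PI}_{\text{post}} = -8.09 + 1.04\,\ln(\mathrm{HE4}) + 0.732\,\ln(\mathrm{CA125}),
$$

with HE4 in pM and CA125 in U/ml (equivalently kU/l). The *predicted
probability* is the percent-scale logistic transform,
$\mathrm{PP} = 100\,e^{\mathrm{PI}}/(1+e^{\mathrm{PI}})$, and a subject is
high-risk when PP meets or exceeds the menopause-specific threshold (12.5%
pre, 14.4% post; closed bound). The model's assumptions are inherited from
its construction: markers must be strictly positive (the logarithms must be
finite) and menopausal status must be known for every scored subject — the
cohort validator enforces both. The coefficients are treated as fixed,
published quantities; `romadx` validates them against data but never
re-estimates them. They are nonetheless configuration
(`roma_coefficients()`, `roma_thresholds()`, `marker_cutoffs()`) so that
alternative thresholds — for example the best-accuracy cutoffs a given cohort
produces — can be swapped in for sensitivity analyses.

Two conventions are worth making explicit because the source material leaves
them open:

- **Single-marker boundary.** Published threshold statements pin down the
  ROMA boundary ("PP ≥ threshold = high risk") but not the single-marker
  one. `classify_marker()` uses *positive iff value ≥ cutoff* so that every
  classifier in the package shares one closed-bound rule.
- **Numerical stability.** PP is computed through the sign-branched logistic
  (`plogis`), so it never overflows and stays strictly inside (0, 100) for
  any log-odds a double can resolve. At extreme log-odds the percent scale
  itself becomes the limit: near $\mathrm{PI} = 30$ the tail probability
  ($\sim 10^{-13}$) sits within one representable gap of PP = 100, so the
  logit round trip through PP carries a relative error of order $10^{-5}$
  there, while for $|\mathrm{PI}| \le 16$ it is accurate to better than
  $10^{-9}$. The tests assert exactly that graded behaviour.

## ROC analysis

All performance indices derive from one calling convention — positive iff
score ≥ cutoff — applied to the `"malignant"` class as cases.

**AUC.** `auc_mann_whitney()` computes the area under the empirical ROC as
the Mann–Whitney statistic (concordant pairs, ties counted half), via the
midrank identity in $O(n \log n)$. This equals the trapezoidal area under
the empirical ROC curve exactly, a property the tests check to $10^{-12}$
against an independent pair-counting loop.

**Variance and paired comparison.** Confidence intervals and the
correlated-AUC test both come from the DeLong placement-value construction:
for each case the fraction of controls it outranks, and vice versa; the AUC
variance is $S_{10}/n_1 + S_{01}/n_0$, and for two markers measured on the
same subjects the variance of the AUC difference replaces the variances by
the paired covariance combination. The test statistic
$z = \Delta\mathrm{AUC}/\widehat{se}$ is referred to the standard normal,
two-sided. This is a fully specified, reproducible choice for "the method
for comparing two correlated ROC areas"; older lookup-table correlation
approximations are asymptotically equivalent but not exactly reproducible.
The implementation is cross-checked in the tests against `pROC`'s
independent DeLong code to $10^{-10}$, and its calibration is verified by
simulation: type-I error of the paired test within 5% ± 1.5% and 95% CI
coverage within ±2%, each over 2,000 replicates at $n = 50/50$ (a size at
which the normal approximation is expected to hold and the suite stays
fast). Intervals use the normal approximation without finite-sample
corrections and are clipped to [0, 1]; a degenerate empirical variance
(perfect separation) yields a flagged point interval rather than a silently
manufactured width.

**Best-accuracy cutoff.** `find_ideal_cutoff()` evaluates every distinct
observed score plus an $+\infty$ sentinel (the all-negative rule) — under
the ≥ convention this spans every achievable confusion matrix, so midpoint
candidates would add nothing. Ties in accuracy are broken by the larger
Youden index, then by the smaller cutoff. Both comparisons are made on
integer numerators (the correct-call count, and $tp \cdot n_0 - fp \cdot
n_1$) because genuinely tied fractions such as $11/12 + 8/12$ and
$10/12 + 9/12$ round differently in floating point and would otherwise break
ties arbitrarily.

## Group statistics

The comparison statistics mirror standard cohort-table practice and are
wrappers around R's own tests, normalised to one result shape:

- `median_iqr()` uses linear interpolation between order statistics
  (quantile type 7). Published tables rarely state their quartile
  convention, so reproduction of such tables is approximate in the last
  decimal.
- `wilcoxon_rank_sum()` enumerates the exact null when the combined sample
  is at most 10 without ties — exactness is cheap there and the tests verify
  it against full enumeration — and otherwise uses the normal approximation
  with tie and continuity correction.
- `chi_square_2xk()` is Pearson's chi-square *without* Yates correction by
  default (a correction flag exists). Characteristic tables in the
  validation literature do not state a correction; with the printed 2×2
  counts for family history, neither the corrected nor the uncorrected
  statistic reproduces some published p-values exactly, so those are treated
  as a documented discrepancy of unknown provenance rather than chased.
- `students_t()` is the pooled-variance test (Welch by flag);
  `students_t_summary()` accepts published mean/sd/n summaries directly.
- Post-hoc pairwise rank-sum comparisons after Kruskal–Wallis are reported
  unadjusted, matching the practice of the validation literature; users can
  apply `p.adjust` if they want familywise control.

## The synthetic cohort

No patient-level data accompany the reference validation study, so the
generator emulates its *published summary structure*:

- **Composition.** 228 benign / 161 malignant subjects; benign histology
  mix 78/66/29/15/13/27 (cystadenoma–cystadenofibroma, endometriosis,
  mature teratoma, fibroma–thecoma, functional cyst, pooled other);
  malignant composition at FIGO-stage resolution (43/8/66/14 within
  epithelial disease, the 4 non-epithelial cases folded into the epithelial
  weights — too few to parameterise separately) plus 26 metastatic tumours;
  post-menopausal fractions 86/228 and 119/161; covariate flag rates at the
  published counts.
- **Marker marginals** are log-normal per group, calibrated from each
  group's published median and IQR by $\mu = \ln(\text{median})$,
  $\sigma = (\ln q_3 - \ln q_1)/(2\,z_{0.75})$. The log-normal form is this
  package's assumption, adopted because the markers are positive and
  heavily right-skewed (medians far below the upper quartiles); it gives
  the calibration a closed form that reproduces the median exactly and the
  quartile *ratio* exactly. A log-normal has multiplicatively symmetric
  quartiles, so the individual quartiles are matched exactly only when
  $q_1 q_3 = \text{median}^2$; the published rows are close to but not
  exactly at that symmetry.
- **Dependence** between CA125 and HE4 is a Gaussian copula at Spearman
  rank correlation 0.3 (benign) / 0.5 (malignant), converted to the latent
  normal correlation by $\rho = 2\sin(\pi r_s/6)$. The reference study
  reports no joint statistics; these defaults encode the qualitative fact
  that both markers rise with malignancy, and they are configurable.
- **Grades.** Borderline tumours are assigned only within early-stage
  (I–II) epithelial cases, with probability $31/51$, and invasive grades at
  13/14/73; this reproduces the published marginal grade mix while placing
  borderline cases in the low-marker early-stage groups — the mechanism
  behind the study's observation that excluding borderline tumours raises
  the ROMA AUC. The published tables do not force this coupling; it is a
  modelling choice.
- **Ages** are normal per class (46.3 ± 16.0 benign, 57.8 ± 12.6 malignant),
  truncated at 18 years by inverse-CDF sampling. ROMA-level medians are
  *not* separately enforced: they emerge from the marker joint distribution
  and the menopause mix.
- **Determinism.** One documented R random stream per `generate_cohort()`
  call, seeded from `config$seed` with a fixed draw order; identical
  configurations give identical cohorts. Pre-analytic covariates
  (haemolysis, freeze delay) are generated independently of the markers at
  the observed rates — the reference study found no association — so they
  exist for schema completeness, not as effects.

What passing tests on this cohort therefore show is that the *machinery* is
correct and that the generator reproduces the summary statistics it was
calibrated to; they do not show that the real cohort's patient-level AUCs
(e.g. ROMA 0.898) are reproduced, because those depend on joint structure
the publication does not report. The end-to-end checks are accordingly
directional: ROMA AUC well above chance (> 0.75) on the default cohort, and
borderline-excluded AUC above the all-malignant AUC on average.

## Pipeline conventions

`run_full_analysis()` evaluates three strata (all, pre-, post-menopausal) ×
three markers (CA125, HE4, ROMA). For the pooled stratum the ROMA ROC and
AUC are computed on pooled PP values — a single score axis — while the
pooled *suggested-cutoff* row classifies each subject at its own
menopause-specific threshold and then pools the confusion matrix. This dual
convention is the only reading consistent with a performance table that
contains both one pooled AUC and stratum-specific suggested cutoffs; the
pooled sensitivity and specificity then necessarily lie between the two
stratum values, which the tests assert. A stratum missing a diagnosis class
is omitted with a warning rather than failing the run. Report rendering
rounds percentages to one decimal and AUCs to three, matching the precision
such tables print.

## Problem sizes and runtime choices

The suite keeps simulation sizes at the smallest scale that still pins down
each property: calibration recovery uses 200,000 draws (the 1% median
tolerance needs roughly that many for a CV comfortably under the band);
Monte-Carlo calibration of the paired test and CI coverage uses 2,000
replicates of 50 + 50 subjects; oracle-equivalence sweeps use 1,000 random
instances of up to ~25 subjects per class. The whole suite runs in well
under a minute on one core.

## Known limitations

- Group-wise log-normality and the copula correlations are assumptions;
  real marker distributions may have heavier tails or menopause-dependent
  correlation, which the configuration cannot currently express
  (`rank_corr` is per group, not per menopausal stratum).
- Age and menopausal status are drawn independently within a class, so the
  synthetic cohort can contain, e.g., young post-menopausal subjects; no
  analysis in the package conditions on that joint behaviour.
- Marker levels are independent of age, covariate flags and subtype within
  a group; subtype-specific marker behaviour (e.g. low HE4 in mucinous
  tumours) is represented only insofar as subtypes correlate with the
  stage groups that carry different marker distributions.
- The DeLong normal approximation is asymptotic; for very small strata the
  flagged degenerate cases are the only finite-sample safeguard.
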