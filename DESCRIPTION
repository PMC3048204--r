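Package: romadx
Title: ROMA Ovarian Cancer Risk Scoring and Diagnostic Performance Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the Risk of Ovarian Malignancy Algorithm (ROMA), which
    combines serum HE4 and CA125 with menopausal status into a predicted
    probability of epithelial ovarian cancer, together with the statistical
    machinery needed to evaluate it as a diagnostic test: empirical ROC curves,
    Mann-Whitney AUC estimation with DeLong-type confidence intervals, paired
    AUC comparison for correlated markers, best-accuracy cutoff search, and the
    rank-based group comparison statistics used in pelvic-mass cohort studies.
    A synthetic cohort generator, calibrated to the composition and per-group
    marker distributions of a published 389-patient validation cohort, makes
    the whole analysis pipeline runnable and testable without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
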