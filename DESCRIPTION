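Package: mcogscore
Title: Digital Cognitive Screening Composite Scores and Their Validation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores a three-part smartphone cognitive screening battery
    (a colour-word Stroop task, a symbol-digit substitution task, and an
    eight-word two-stage cued recall task), combines the subtest scores
    into a z-score composite (the M-CogScore), and validates the composite
    against the Mini-Mental State Examination (MMSE-2) and Clinical
    Dementia Rating (CDR) labels.  Includes a synthetic case-control
    cohort generator with a latent-severity model, impairment-dependent
    section skipping and upload failures; the classical test battery used
    in screening validation (Spearman, Mann-Whitney U, Fisher exact,
    Yates-corrected chi-squared, t-test, Shapiro-Wilk, proportional median
    difference); empirical ROC curves with Youden cut-offs, stratified
    proportion-bootstrap confidence intervals and the paired DeLong test;
    and an end-to-end study pipeline with exclusion accounting, a Table-1
    style summary and a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
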