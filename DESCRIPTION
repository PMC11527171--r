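Package: betapet
Title: Behavioral Task-Associated PET Differential Uptake Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for behavioral task-associated PET (beta-PET): paired
    baseline/recall FDG-PET scans are normalized to the whole-brain mean,
    regional standard uptake values are extracted per coronal slice and
    hemisphere, and their difference (delta-SUV) quantifies the
    task-associated metabolic response. Includes freezing-bout scoring of
    frame-wise activity traces, nested linear mixed-model group inference,
    delta-SUV/freezing correlations, leave-one-out cross-validated
    classification (ridge logistic, linear SVM, GentleBoost) with
    scrambled-label controls, ordinal-trends canonical variates analysis
    (AIC pattern selection, label-flip permutation test, subject-level
    bootstrap of voxel weights), and a synthetic-cohort generator with
    known planted effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    lme4,
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
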