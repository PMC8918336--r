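Package: kmindex
Title: CT-Perfusion-Based Prediction of Midline Shift After MCA Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the KM index, a CT-perfusion-derived risk score for
    midline shift after middle cerebral artery infarction. The index relates
    infarct core, penumbra and perfused brain volumes to the scanned
    intracranial volume, weighted by the reperfusion result (mTICI grade),
    intravenous thrombolysis and optionally the onset-to-groin time. The
    package provides per-patient index, score and risk-class computation,
    voxel-based volumetry from NIfTI label maps, cohort table handling with
    explicit inclusion/exclusion filtering, correlation-based calibration of
    the index parameters against measured midline shift, threshold and
    ROC/AUC evaluation, a seeded synthetic cohort generator with the
    statistical structure of a realistic stroke cohort, and a command-line
    interface binding these pieces into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    RNifti,
    ggplot2,
    optparse,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
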