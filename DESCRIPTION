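Package: fnirsglucose
Title: Prefrontal fNIRS Preprocessing and Glucose Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying the association between prefrontal-cortex
    hemodynamics measured by dual-wavelength (760/830 nm) functional
    near-infrared spectroscopy (fNIRS) and blood glucose under fasting and
    glucose-loaded conditions. Provides a seeded synthetic cohort generator
    (glucose excursion curves, glucose-coupled oxyhemoglobin responses,
    physiological oscillations, motion artifacts), a Homer2-style
    preprocessing chain (channel pruning, optical density conversion,
    wavelet motion correction, band filtering, modified Beer-Lambert
    inversion, correlation-based signal improvement), two-sample channel
    selection, ten time-series features of the oxyhemoglobin signal,
    decreasing-rule principal component analysis (PCA eigenvectors re-ranked
    by a between/within-class scatter ratio), matrix-form Pearson
    association, and nested leave-one-subject-out evaluation of glucose
    predictors with RMSE, MARD and correlation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    data.table,
    class,
    caret,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
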