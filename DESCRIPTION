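Package: erpmoca
Title: MoCA-Equivalent Cognitive Scores from Single-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Montreal Cognitive Assessment (MoCA) scores from
    single-channel auditory event-related potentials (ERPs). Implements a
    multi-trial branch (epoching, baseline correction, artifact rejection,
    grand averaging, 0-30 Hz filtering, prominent-point and windowed
    time-domain feature extraction, lasso feature selection, and four
    cross-validated regressors with residual diagnostics) and a single-trial
    branch (response-time/range trial filtering, time-frequency images, a
    compact convolutional network regressor, and Gaussian-process Bayesian
    optimization of its hyperparameters via Expected Improvement). Ships a
    synthetic cohort generator with planted MoCA-dependent ERP effects so the
    full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    e1071,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pracma,
    withr
Config/testthat/edition: 3
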