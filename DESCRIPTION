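Package: relaxEEG
Title: Frontal EEG Relaxation-State Features, Group Contrasts, and
    Stacked LOSO Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying a self-reported relaxation state
    (R-state, 1-9) from three-channel prefrontal EEG (FP1, FPZ, FP2).
    Provides a synthetic session generator with a latent relaxation
    trajectory, Butterworth band-pass preprocessing into seven canonical
    bands, a per-second spectral feature bank (energy, energy ratios,
    energy entropy, differential entropy, autoregressive power spectral
    density, and hemispheric asymmetries), paired viewing-contrast
    statistics with cross-participant consistency detection,
    sliding-window data enhancement, and leave-one-subject-out
    evaluation of eight regressors plus a two-level stacking framework
    scored by mean absolute error and mean relative accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    ranger,
    rpart,
    xgboost,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
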