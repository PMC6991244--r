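Package: restpredict
Title: Resting-State EEG Prediction of Antidepressant Treatment Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting antidepressant treatment outcome from
    resting-state electroencephalography (EEG). Implements a complete,
    reproducible analysis pipeline: simulation of multi-site EEG cohorts
    with known ground-truth group effects; harmonization and artifact
    cleaning of multichannel recordings; four classes of EEG features
    (electrode-level band power and hemispheric lateralization, eLORETA
    source-space band power, multiscale entropy over 70 timescales with
    hemispheric asymmetry, and microstate statistics); stability-voting
    feature ranking based on repeated subsample t tests; RBF-kernel
    support vector machine classification evaluated with nested
    stratified k-fold and leave-one-site-out cross-validation; and a
    Monte Carlo estimator of the outcome-label-noise ceiling on
    achievable balanced accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
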