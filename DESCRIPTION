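Package: seizentropy
Title: EEG Entropy Pipeline for Discriminating Psychogenic Non-Epileptic
    from Epileptic Seizures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end EEG complexity pipeline for
    separating psychogenic non-epileptic seizures (PNES) from epileptic
    seizures (ES): nine entropy estimators (sample, fuzzy, permutation,
    dispersion, conditional, phase, spectral, Renyi and wavelet entropy)
    computed on 5-second epochs of 17-channel scalp EEG; interictal,
    preictal and dynamic (preictal minus interictal) state contrasts;
    nonparametric group statistics with rank-biserial effect sizes and
    Benjamini-Hochberg correction; and a leakage-free leave-one-subject-out
    classification harness with subject-level undersampling, nested
    tuning, permutation-based channel selection, threshold calibration by
    the geometric mean of sensitivity and specificity, and hard-vote
    aggregation of epoch predictions. A synthetic cohort generator with a
    controllable group-by-state complexity structure makes every stage
    testable without clinical recordings, and a minimal 16-bit EDF
    writer/reader supports on-disk round trips.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    MASS,
    e1071,
    class,
    nnet,
    ranger,
    xgboost,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
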