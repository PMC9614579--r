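Package: crywatch
Title: Newborn Cry Acoustics and Machine Learning Assessment of Neonatal
    Opioid Withdrawal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting pharmacological treatment of neonatal
    opioid withdrawal syndrome (NOWS) from newborn cry acoustics. Provides
    a synthetic cry-audio cohort generator (source-filter synthesis with
    controllable pitch, hyperphonation, formant, fricative and utterance
    structure), frame-level acoustic analysis in 12.5 ms frames under two
    configurable analyzer profiles (cepstral and spectral pitch tracking,
    linear-prediction formants, band energies, spectral entropy, fricative
    scoring, amplitude envelope and spectral novelty), energy-based cry
    utterance segmentation with short/long stratification, feature
    filtering (missingness, near-zero variance, intercorrelation), a
    native Boruta shadow-feature selector with a 100-repetition retention
    ensemble and per-fold stability estimates, stacked random-forest
    classification under leave-one-out cross-validation, and diagnostic
    evaluation (ROC/AUC with DeLong intervals, distance-to-perfect
    cutpoint, exact binomial confidence intervals, Cohen's kappa, and
    subgroup sensitivity analyses).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ranger,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
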