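Package: sipfft
Title: Self-Interacting Protein Prediction from PSSM Spectral Features
    with a Random-Projection Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of self-interacting proteins (SIPs).
    Parses PSI-BLAST ASCII position-specific scoring matrices (PSSMs) or
    builds Dayhoff-matrix fallback profiles from bare sequences, summarises
    each protein as the 20x20 Gram matrix of its PSSM, extracts fixed-length
    spectral descriptors (2-D FFT modulus primary; DCT, SVD and column-
    covariance comparison extractors), reduces them by PCA, and classifies
    with an ensemble of k-nearest-neighbour learners trained on unit-norm
    random projections, each selected by leave-one-out error from a block of
    candidates and aggregated with a prevalence-derived voting threshold.
    Includes an RBF-SVM baseline, stratified k-fold cross-validation with
    undersampling, confusion-matrix metrics (accuracy, sensitivity,
    specificity, MCC, balanced accuracy), ROC/AUC, and a seeded synthetic
    PSSM generator with class-dependent periodic structure for offline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
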