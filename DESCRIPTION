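Package: ProtNPCA
Title: Nonnegative Principal Component Analysis for Mass Spectral Serum
    Profiles and Biomarker Discovery
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements nonnegative principal component analysis (NPCA) with
    Hoyer sparse coding for mass spectral serum proteomic profiles, an
    NPCA-SVM proteomic pattern classifier evaluated under repeated holdout
    cross-validation against standard peer algorithms (k-NN, SVM, PCA-SVM,
    NMF-SVM, ICA-SVM, PCA-LDA), and an NPCA-based filter-wrapper biomarker
    capturing algorithm combining a closed-form two-sample Bayes factor
    filter, variance-weighted NPCA loading ranks, and greedy forward
    selection under SVM leave-one-out cross-validation. Includes seeded
    generators for serum-profile-like synthetic data with planted
    biomarkers, delimited-text I/O for labeled intensity matrices, and a
    command-line interface for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    SummarizedExperiment,
    S4Vectors,
    e1071,
    MASS,
    class,
    pracma,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Classification, FeatureExtraction,
    DimensionReduction, SupportVectorMachine
RoxygenNote: 7.3.3
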