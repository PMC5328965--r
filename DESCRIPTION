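Package: connMVPA
Title: Multivariate Pattern Analysis of Resting-State Functional Connectivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A connectome-based multivariate pattern analysis (MVPA) pipeline
    for paired resting-state fMRI designs: region-of-interest time-series
    preparation (initial-volume discard, nuisance regression, Chebyshev
    band-pass filtering, frame-wise-displacement scrubbing, atlas
    parcellation), Fisher-z transformed Pearson connectivity features,
    Kendall-tau discriminative feature scoring with top-K selection,
    RBF-kernel support vector classification under leave-one-out
    cross-validation with nested feature selection, whole-pipeline
    permutation testing of classifier significance, and consensus-connection
    and region-weight reporting. Includes a synthetic-data generator that
    plants known pre/post connectivity effects so that every stage of the
    pipeline is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, Network, FeatureExtraction, fMRI
RoxygenNote: 7.3.3
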