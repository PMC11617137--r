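Package: vrsa
Title: Variational Representational Similarity Analysis for
    Reach-Planning fMRI Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian pattern component modelling (variational
    representational similarity analysis) of condition-by-voxel activity
    patterns from a delayed reach-to-target fMRI experiment with a 2x2x2
    hand/target/gaze factorial. Provides factorial trial-type enumeration
    with task-board geometry, variance-inflation-factor (VIF) optimisation
    of event-related run designs, canonical-HRF design matrices and
    ordinary-least-squares beta estimation, rank-one component model
    matrices for direction and relative-distance hypotheses, variational
    ReML estimation of covariance-component weights with Bayesian model
    reduction scoring of each component's log evidence, shuffle-null log
    Bayes factors with the "three times more credible" decision criterion,
    and a synthetic-data generator with planted direction/distance
    encoding for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    Rcpp,
    jsonlite,
    RNifti,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
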