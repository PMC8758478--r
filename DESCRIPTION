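Package: LfAPP
Title: APP-Lactoferrin Binding Biophysics and Outlier-Robust Transcriptomic
    Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the two computational arms of an APP-lactoferrin
    interaction study. The biophysics arm provides Svedberg/Stokes
    hydrodynamic mass inference, finite-volume Lamm-equation simulation of
    sedimentation-velocity scans, regularized non-negative c(s)
    deconvolution, weight-average sedimentation coefficients, and
    two-site equilibrium binding models fitted to sedimentation and
    tryptophan-fluorescence titrations. The transcriptomic arm provides TMM
    normalization, empirical-Bayes batch correction, negative-binomial
    differential expression with covariates, a from-scratch Boruta
    shadow-feature selection over random-forest importances, and the
    Boruta-versus-DEA rank comparison, together with synthetic-data
    generators that emulate a sentinel gene whose control-group expression
    is concentrated in a few outlier samples.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    edgeR,
    ranger,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
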