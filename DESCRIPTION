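Package: mvpatime
Title: Time-Resolved Multivariate Pattern Analysis for Multichannel
    Neural Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-resolved multivariate decoding of epoched
    multichannel recordings such as EEG. Provides a synthetic-data
    generator with planted object- and category-level representational
    dynamics, artifact rejection and anti-aliased downsampling,
    super-trial (pseudo-trial) averaging, multivariate noise
    normalization with analytic covariance shrinkage, pairwise linear
    support-vector decoding at every timepoint (within-modality,
    cross-modal, and full temporal generalization), and group-level
    nonparametric inference via sign-flip cluster-size permutation
    tests and bootstrap peak-latency comparisons. An end-to-end,
    config-driven pipeline reproduces complete simulated decoding
    studies from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
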