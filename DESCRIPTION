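Package: popinfo
Title: Information-Theoretic Analysis of Neural Population Coding and Transmission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate information-theoretic measures for trial-structured
    neural data: Shannon entropy and mutual information from discretized
    (plugin) probabilities; limited-sampling bias corrections (shuffle
    subtraction, Panzeri-Treves, quadratic extrapolation, bootstrap
    subtraction); partial information decomposition on the Williams-Beer
    redundancy lattice; information breakdown into signal-similarity and
    noise-correlation components; redundancy-synergy index; intersection
    information between stimulus, neural activity and choice; transfer
    entropy and feature-specific information transfer with conditional
    variants and time-resolved delay sweeps; hierarchical shuffling null
    models with permutation tests; decoder-based (SVM/GLM) confusion-matrix
    population information with unsupervised dimensionality reduction; and
    seeded ground-truth simulators of correlated spike-count populations and
    a four-node delayed-communication network for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
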