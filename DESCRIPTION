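Package: pcanet
Title: Peer Change Agent Selection on Partially Observed Friendship Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying peer change agents (PCAs) on undirected
    friendship networks in which ties among non-surveyed individuals are
    unobserved, as in Facebook friend-list data collected from a
    respondent-driven sample. Implements degree-based boundary specification
    for nonrespondent inclusion, maximum-likelihood estimation of a
    dyad-independent exponential random graph model (edges, sociability,
    selective mixing), model-based multiple imputation of the unobserved
    nonrespondent-nonrespondent dyads, PCA selection by eigenvector
    centrality and the keyplayer-positive set measure, and
    sensitivity/stability evaluation of the selected sets across imputed
    networks. A seeded synthetic-network generator with known ground truth
    supports end-to-end testing and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
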