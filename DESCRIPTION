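Package: ryrcluster
Title: Stochastic Gating of RyR2 Calcium-Release-Channel Clusters
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact stochastic simulation of clusters of cardiac ryanodine
    receptor (RyR2) channels modelled as coupled four-subunit tetramers.
    Each subunit is a two-state (open/closed) unit with Ising-like
    cooperative coupling to its ring neighbours within a channel and to
    contact subunits of adjacent channels, with calcium-induced calcium
    release feedback through a well-mixed dyadic calcium pool. The package
    builds the cryo-EM-motivated adjoining and oblique cluster
    architectures, bond-diluted and preferential-attachment morphologies,
    runs an exact Gillespie simulation with incremental propensity updates
    to measure first-passage (waiting) times to spontaneous calcium spark
    initiation, and validates the engine against a brute-force
    continuous-time Markov-chain solver for small systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
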