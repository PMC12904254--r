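Package: coevoscape
Title: Fitness-Landscape Inference and Geometry for Library-on-Library
    Protein Coevolution Selections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing synthetic protein-protein coevolution
    experiments in which two randomized libraries are selected against each
    other over multiple rounds and read out by deep sequencing. Provides a
    selection probabilistic model (SPM) that infers a sequence-to-fitness
    function from multi-round read counts via a multinomial likelihood with
    a neural parametrization; functional-ANOVA epistasis decomposition with
    intra- and inter-chain importance summaries; greedy adaptive-walk
    simulation with per-sequence accessibility; energy-well depth and
    accessibility statistics with bootstrap comparison tests; hypergeometric
    pair-enrichment filtering and sequence-similarity-network clustering;
    seed-sequence identification along coevolutionary paths; inter-chain
    atomic contact classification for complex structures; and a synthetic
    multi-round selection simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    igraph,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
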