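Package: planktonNCP
Title: Linking Eukaryotic Plankton Community Composition to Net Community
    Production
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline connecting 18S OTU community composition to
    mixed-layer net community production (NCP) in polar surface oceans. Provides
    O2/Ar-based NCP flux estimation (biological oxygen supersaturation, Garcia-
    Gordon O2 solubility, quadratic wind-speed gas transfer with mixed-layer
    ventilation weighting, density-threshold mixed layer depth, POC-normalized
    NCP), Bayesian stochastic-search variable selection (spike-and-slab Gibbs
    sampling with posterior inclusion probabilities and sharp-drop selection),
    forward-stepwise AICc regression, adjusted-R2 variance partitioning, SparCC
    compositional co-occurrence networks with permutation p-values and graph
    topology metrics, and a seeded synthetic-data generator with planted ground
    truth for end-to-end validation.
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
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
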