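Package: csar
Title: Correlation Set Analysis for Detecting Active Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects causal regulators that are active in a population of
    expression profiles by combining a literature-derived causal network
    with co-expression analysis of each regulator's regulatees
    (Correlation Set Analysis, CSA). Regulators are scored by the mean
    absolute pairwise Pearson correlation of their regulatees or by the
    fraction of regulatee pairs whose absolute correlation exceeds a
    dataset-global cutoff. Significance is assessed by gene permutation
    or by degree-preserving edge-switch randomization of the causal
    network, with Benjamini-Hochberg control of the false discovery
    rate. Includes a simulation framework (label-permutation baselines,
    Cholesky/Iman-Conover correlation spike-in, synthetic heavy-tailed
    causal networks) and evaluation utilities (ROC curves, empirical
    FDR checks, out-degree baseline ranking, Fisher's exact signature
    enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    optparse
Config/testthat/edition: 3
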