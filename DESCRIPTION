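Package: rwmrp
Title: Gene Prioritization by Random Walk with Multi-Restart Probabilities on Multiplex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network propagation for candidate gene prioritization on multiplex
    (multi-layer, shared-node) biological networks. Implements a random walk in
    which each node's restart probability is derived from its per-layer
    eigenvector centrality, alongside the classical uniform-restart random walk
    with restart (RWR) baseline, a leave-one-out cross-validation harness with
    top-k cumulative rank curves, an interaction-score candidate filter, and a
    synthetic multiplex generator with a planted response module for
    ground-truth benchmarking. Layers are read from plain TSV edge lists;
    co-expression layers can be built from expression matrices by Pearson
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    ggplot2,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
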