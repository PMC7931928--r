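Package: dn2cn
Title: Causal Bayesian Network Learning via Dependency Networks and Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns causal Bayesian networks over fully observed discrete data by
    first fitting a dependency network of depth-limited probability trees (one
    tree-structured conditional per variable, capturing context-specific
    independence), then converting the possibly cyclic dependency network into a
    directed acyclic graph: bidirected edges are collapsed to undirected ones,
    pairwise mutual information scores every adjacency, an automatic threshold is
    selected at the largest gap in the sorted score list, directed cycles are
    broken shortest-first by deleting weak edges, and remaining undirected edges
    are oriented while preserving acyclicity. Fitted networks carry tree
    conditionals estimated by maximum likelihood (optionally Laplace-smoothed),
    support forward sampling and joint log-likelihood, and come with bundled
    ground-truth benchmark networks and orientation-sensitive structure-recovery
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
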