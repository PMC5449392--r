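Package: netprior
Title: Consensus Centrality and Ontology-Guided Disease-Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds confidence-filtered protein-protein interaction networks
    over candidate gene sets, characterizes their (scale-free) topology, ranks
    genes by eleven node centralities combined into a rank-sum consensus,
    performs two-list hypergeometric Gene Ontology enrichment with term-size
    filtering and information-content based redundancy pruning, predicts
    disease candidate genes by set logic over top-ranked and
    enrichment-derived gene sets, and validates rankings against per-gene
    disease-association counts binned by consensus rank. A seeded synthetic
    study generator (preferential-attachment network with hub-biased disease
    genes, a planted-enrichment annotation corpus, and rank-correlated
    disease counts) makes the whole pipeline runnable and testable without
    external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
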