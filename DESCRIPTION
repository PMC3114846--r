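Package: dgnet
Title: Gene-Disease Network Construction, Clustering and Modularity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds bipartite gene-disease association networks from
    multi-source association tables, projects them to weighted monopartite
    gene and disease networks using the overlap coefficient, detects
    disease and gene modules with the Markov Cluster algorithm, and
    quantifies functional modularity through pathway homogeneity and an
    interaction-network connectivity score (HINscore) with size-matched
    resampling null models, binned summaries and over-representation
    analysis. Includes a synthetic-data generator with planted pathway
    structure for validating the whole pipeline against known ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
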