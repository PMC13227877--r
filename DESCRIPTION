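Package: ianinet
Title: Imbalance-Aware Network Integration for Cancer Driver Gene Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts cancer driver genes from protein-protein interaction
    networks. Builds a high-confidence gene interaction graph from STRING-style
    edge lists, extracts eight per-gene topology features (degree, betweenness,
    PageRank, k-core, clustering coefficient, closeness, eigenvector
    centrality, triangle count), and trains an imbalance-aware ensemble: SMOTE
    minority oversampling, Latin hypercube stratified undersampling of the
    majority class, class weighting, a focal-loss neural network, weighted
    soft voting over four base learners, and an F1-optimised decision
    threshold. Includes hub-gene statistics (mean + 2 SD outdegree calling,
    ego networks, enrichment with effect sizes), degree-matched random null
    models, external gene-set evaluation, and a planted-signal synthetic
    network generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    lhs,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
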