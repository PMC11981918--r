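Package: perisoma
Title: Perisomatic Ultrastructure Features for Cell-Type Classification in
    Dense EM Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts nucleus, soma and postsynaptic-shape (PSS) features from
    labeled 3-D electron-microscopy segmentation volumes and synapse tables,
    classifies cells with a five-model hierarchical cascade, and searches the
    standardized feature space for rare connectivity-defined cell types such
    as chandelier cells. Includes nuclear-infolding quantification via
    shrink-wrap envelope meshes, a bag-of-shapes dictionary over pose-normalized
    postsynaptic shapes, synapse-soma angular targeting statistics with exact
    Fisher enrichment, proofreading and truncation statistics, and a synthetic
    phantom generator that provides analytic ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    withr,
    generics,
    igraph,
    mclust,
    MASS,
    e1071,
    randomForest,
    rpart,
    nnet,
    class,
    RANN,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
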