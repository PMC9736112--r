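Package: wgdnet
Title: Coexpression Networks of Gametogenesis Genes in Polyploid Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking whole-genome duplication (WGD) in tumours to
    coordinated expression of gametogenesis-related (GG) genes. Assembles and
    deduplicates GG gene catalogues, filters differential-expression tables at
    fixed inferential/effect-size thresholds, tests GG enrichment among
    ploidy-up- and downregulated genes with exact binomial tails, profiles
    gene sets over phylostrata, calibrates a hard correlation threshold for
    coexpression networks against column-shuffled surrogate data, extracts
    giant components and Cytoscape-convention network metrics, clusters
    networks with a deterministic Markov Cluster (MCL) implementation, and
    performs hypergeometric over-representation analysis with Holm step-down
    correction. Includes proteome preparation (tree-cut sample stratification,
    low-expression filtering, minimum imputation) and seeded synthetic-data
    generators with planted ground truth for parameter-recovery testing.
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
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
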