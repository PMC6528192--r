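Package: gdagnet
Title: Genome-Anchored Causal Networks for Metabolomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for tracing loss-of-function genetic variation to serum
    metabolite levels through causal networks. Implements penalized and
    single-variant selection of gene-metabolite associations with Bonferroni
    control, construction of principal-component instrumental variables from
    linkage-disequilibrium-pruned genotypes, constraint-based learning of a
    metabolomic causal network anchored by those instruments (PC-stable
    skeleton search, collider orientation and Meek propagation), structural
    Hamming distance tuning of the conditional-independence level, structural
    equation modeling to separate direct from mediated gene effects
    (pleiotropy assessment), and module detection on the learned network. A
    synthetic-data generator with known causal ground truth supports
    validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
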