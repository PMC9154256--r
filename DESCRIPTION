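Package: deepgofs
Title: Deep Functional Similarity of Genes from Gene Ontology Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional embeddings of Gene Ontology (GO) terms and
    gene products and predicts functional similarity of gene pairs with a
    paired (Siamese) neural network that shares weights across the two genes
    of a pair and aggregates their annotation embeddings through max-pooling,
    dense layers and a sigmoid-gated highway layer. Includes a definition-based
    embedding pretraining pipeline (second-order word features, positive
    pointwise mutual information, latent semantic analysis), parsers for OBO
    ontologies and GAF annotation files with evidence-code filtering and
    ancestor lifting, builders for protein-protein interaction, sequence
    homology (log-reciprocal and relative-reciprocal BLAST bitscores) and
    co-expression (Fisher-z) benchmark datasets, a protein-grouped
    cross-validation protocol that prevents pair leakage, and a fully
    synthetic data generator with known latent structure for end-to-end
    validation.
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
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
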