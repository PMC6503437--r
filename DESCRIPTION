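Package: genesurrounder
Title: Network-Based Identification of Disruptive Genes in Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the GeneSurrounder algorithm for ranking genes as
    putative sources of dysregulation on a molecular interaction network.
    For every gene and every geodesic neighborhood radius the method combines
    a gene-resampling test of the gene's Spearman correlation with its
    network neighbors (sphere of influence) with a phenotype-permutation test
    of distance-decaying differential expression (Kendall tau-b discordance),
    merges the two empirical p-values by Fisher's method, and reports each
    gene's minimum combined p-value across radii with a diameter-scaled
    Bonferroni significance call. Includes readers for delimited expression,
    phenotype and edge-list/SIF network files, a missing-data filter, a
    synthetic-data generator with planted driver genes for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
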