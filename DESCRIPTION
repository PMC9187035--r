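Package: coevgraph
Title: Phylogeny-Weighted Amino Acid Covariance Graphs and Functional-Site
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes phylogeny-weighted amino acid covariance metrics
    (mutual information, chi-squared, and PSSM-based Pearson correlation)
    from a query-anchored multiple sequence alignment, regularizes them by
    graphical-LASSO sparse inverse covariance estimation with automatic
    penalty selection, builds covariance-threshold residue graphs with
    maximal-clique enumeration, and quantifies coevolution of residues
    sharing a molecular function (ligand binding) through log-odds
    enrichment statistics. Includes a synthetic-alignment generator with
    planted covarying column pairs for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
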