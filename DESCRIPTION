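Package: dualgene
Title: Comparative Profiling of Dual-Role Cancer Genes Across Mutation,
    Expression and Interaction-Network Axes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare genes with dual oncogenic and tumor-suppressor
    roles (POTSFs) against oncogenes, tumor-suppressor genes and non-cancer
    genes. Builds disjoint gene-set partitions from curated lists, profiles
    somatic mutation burden and per-gene mutation rates from MAF-like tables,
    normalizes RSEM/RPKM expression matrices (median scaling, per-organ
    log2 Z-scores), computes protein-protein interaction network properties
    (degree, clustering coefficient, MCODE-style dense-module detection) and
    Nei-Gojobori dN/dS, and runs the Kolmogorov-Smirnov / Wilcoxon /
    chi-square set comparisons with significance annotation. A synthetic-data
    module generates gene universes, mutation tables, expression matrices,
    hub-biased interactomes and codon pairs with known structure so that
    every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    igraph,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
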