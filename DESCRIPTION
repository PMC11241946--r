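Package: regmark
Title: Linking Histone-Modification and Open-Chromatin Peaks to Gene
    Expression, Protein Evolution and Nucleotide Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for the downstream analysis of
    CUT&Tag and ATAC-seq peak calls in two-ecotype population designs.
    Classifies peaks into genomic-feature categories by their centers,
    associates peaks with gene expression (TPM) and protein evolutionary
    rates (dN/dS), computes nucleotide diversity (pi) and between-population
    divergence (Dxy) in fixed genomic windows, clusters samples by binned
    genome-wide coverage, and screens for ecotype-specific genes with
    candidate cis-regulatory indels. Includes a synthetic-data generator
    that emulates the statistical structure of such experiments with known
    ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
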