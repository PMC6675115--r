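Package: extremediff
Title: Family-Contrast Differential SNV Screening and Candidate Gene
    Prioritization for Extreme Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an extreme-phenotype sib-family contrast pipeline for
    whole-genome variant calls: per-sample SNV call filtering (base quality,
    read depth, alt-supporting reads), identification of common differential
    SNVs (sites fixed for opposite alleles between high- and low-breeding-value
    sibs across all families), gene-model functional annotation with
    coding-effect calling, hypergeometric over-representation analysis of the
    implicated genes against gene-set collections with pathway-whitelist
    rescue, and physical-to-genetic-map interpolation with a QTL-peak
    proximity rule, ending in a ranked candidate-gene table. A synthetic-data
    module generates a fully self-consistent study (reference, gene models,
    cohort VCFs, gene sets, genetic map, QTL table) with known planted truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
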