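Package: mitoscan
Title: Case-Control Association Scanning for Whole Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for case-control analysis of aligned
    whole-mitogenome cohorts: per-position allele-frequency-difference (delta)
    scanning with 3-SD outlier flagging, per-site contingency statistics with
    odds ratios and Woolf or exact confidence intervals, Wright's FST over
    haplogroup frequencies and AMOVA-style PhiST from pairwise sequence
    differences with permutation nulls, haplogroup classification against a
    user-supplied definition tree with simplified macro-lineage collapsing,
    codon-level consequence annotation under the vertebrate mitochondrial
    code with codon-usage ratios, and a seeded synthetic cohort generator
    with machine-readable ground truth for end-to-end validation.
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
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    vcfR,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
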