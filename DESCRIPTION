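Package: methylquad
Title: Integrative Methylation-Expression Analysis for Subtype-Specific
    Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for nominating subtype-specific,
    prognosis-associated genes from capture-based (MBD-seq style) DNA
    methylation counts and matched expression profiles. Converts
    region-of-interest read counts to CpG-density-corrected absolute
    methylation scores, calls hyper- and hypomethylated genes per tumor
    subtype with paired t-tests and Benjamini-Hochberg correction,
    partitions calls by CpG-island and promoter/gene-body context,
    integrates methylation with expression into four quadrant groups,
    screens candidates for subtype specificity, stratifies survival by
    composite methylation-expression risk rules with from-scratch
    Kaplan-Meier and log-rank machinery, and calibrates percent
    methylation from melting-curve peak areas against standards. Ships a
    synthetic paired-cohort generator with planted truth so the whole
    workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
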