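Package: hormsynergy
Title: Coordinated Thyroid Hormone and Glucocorticoid Transcriptional
    Synergy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for replicated four-treatment (vehicle,
    T3, corticosterone, combined) expression experiments: fold-change and
    Welch-test differential expression filtering, three-way Venn
    partitioning of hormone-regulated gene lists with intersection
    refinement into regulation-pattern codes, a two-criterion synergy
    caller (combined-only response, or greater-than-additive response
    with a variance-sum Welch test and a standard-deviation margin), and
    a ChIP-peak proximity analysis scoring receptor/enhancer-mark
    co-localization in gene-body +/- 50 kb windows. Includes synthetic
    generators for expression matrices and peak tracks with
    machine-readable truth labels so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
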