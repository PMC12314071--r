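Package: crmscreen
Title: Screening Cis-Regulatory Modules and Core-Promoter Elements in Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for locating compact cis-regulatory modules (CRMs) that
    pattern cell-type-specific expression in plant genomes. Provides position
    weight matrix construction with exact occurrence p-values computed by
    dynamic programming, strand-aware motif scanning, annotation of core
    promoter elements (pyrimidine Y-patches, TATA-box variants, MTE, BREu and
    DCE-S-I), a six-family motif co-occurrence caller restricted to accessible
    chromatin, expression-class filters for cell-separated RNA-seq summary
    tables, enrichment testing, and quantification of fluorometric reporter
    assays with compact-letter group comparisons. Ships a synthetic-data
    generator that plants motifs, expression classes and kinetic rates with
    known ground truth so the full pipeline can be exercised end to end.
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
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
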