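Package: nascentrip
Title: Comparative Poisson Peak Calling and Localization Analysis for RIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing RNA immunoprecipitation sequencing (RIP-seq)
    experiments against an IgG mock control. Implements a comparative Poisson
    peak caller (library-size matching by downsampling, +/-150 bp smoothed
    coverage, fold-enrichment and Poisson seeding, fold-bounded extension, and
    cross-replicate reproducible-peak merging), a gene-feature annotator for
    called peaks, a nuclear/cytoplasmic RNA localization classifier based on
    RPM-normalized fractionated RNA-seq counts, preparation of foreground and
    background sequence sets for differential motif discovery, and a seeded
    synthetic-data generator so the whole pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
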