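Package: magdistill
Title: Distillation of Metabolic Annotations for Microbial and Viral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns per-database homology and profile-HMM search results for
    called genes into distilled, genome-level metabolic summaries. Provides
    confidence ranks (A-E) for merged gene annotations based on reciprocal
    best hits and bit-score thresholds, KEGG-style module parsing with
    pathway step coverage and directed-network best-path completion,
    MIMAG-style genome quality ranks, per-genome function-identifier count
    tables organized by metabolic category, and a rule-based caller for
    putative auxiliary metabolic genes (AMGs) on viral contigs using
    flanking viral evidence, auxiliary scores 1-5 and curation flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    igraph,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
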