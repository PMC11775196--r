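Package: proxiscore
Title: Spectral-Count Interaction Scoring and ChIP-Seq Targetome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for transcription-factor multi-omics:
    scores bait-prey pairs from AP-MS and proximity-labeling (BioID/UltraID)
    spectral counts with a two-component Poisson posterior-odds model and a
    Bayesian false discovery rate, applies a high-confidence-interaction filter
    ledger (BFDR thresholds, cross-bait rescue, contaminant-frequency filtering
    with a spectral-count override, minimum-count rule), compares interactomes
    across baits, labeling times, cell lines and isoforms (Venn partitions,
    replicate correlation, stability scores, isoform volcano analysis), and
    integrates ChIP-seq targetomes (peak overlap groups, nearest-TSS annotation,
    top-N target genes, lost/shared/gained classification, peak-centered signal
    matrices, degenerate palindromic motif scanning with variable spacers) with
    hypergeometric gene-set enrichment. Includes seeded synthetic-data
    generators with exhaustive ground truth so the full pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
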