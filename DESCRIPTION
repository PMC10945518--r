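Package: nucpioneer
Title: Pioneer Transcription Factor Detection from Nucleosome-Resolved
    Chromatin Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates MNase-seq-derived nucleosome dyad positions,
    DNase-seq-derived open chromatin, and ChIP-seq-derived transcription
    factor (TF) binding motifs to score each TF's propensity to bind
    nucleosomal DNA. Maps representative nucleosome dyads by triweight
    kernel smoothing of fragment-midpoint counts, annotates
    nucleosome-depleted regions (NDRs) and differentially open chromatin,
    scans peak sequences with JASPAR position weight matrices using exact
    dynamic-programming p-values, computes a per-base odds-ratio enrichment
    score of motif coverage on nucleosome regions versus NDRs with Fisher
    exact tests, builds dyad-anchored binding-motif profiles with
    superhelical-location summaries, and clusters TFs by nucleosomal
    binding mode with t-SNE and k-medoids. Ships a fully synthetic data
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    Rtsne,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
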