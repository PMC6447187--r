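Package: dstile
Title: Off-Target-Minimized dsRNA Trigger Design and RNAi Knockdown Quantification
Version: 0.1.0
Authors@R: person("dstile", "developers", role = c("aut", "cre"),
    email = "dstile@example.org")
Description: Design tools for RNA interference triggers in non-model insects.
    Tiles a target cDNA into 19-nt fragments, screens every fragment against a
    transcriptome for approximate matches that could silence unintended genes
    (seed-and-extend matcher with a brute-force alignment oracle, or imported
    BLAST tabular hits), maps accepted hits back onto the target, and selects
    the amplicon window carrying the fewest potential off-target silencing
    fragments before tagging primers with a T7 promoter for in vitro
    transcription. A companion qPCR module computes efficiency-aware relative
    expression by the 2^-ddCt method against a reference gene and calibrator
    group, fits amplification efficiencies from standard-curve slopes, and
    compares treatment groups with Shapiro-Wilk-gated t or Mann-Whitney tests.
    Synthetic-data generators provide transcriptomes with planted homologous
    blocks and Cq tables with known knockdown fractions so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
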