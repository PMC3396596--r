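Package: hesfam
Title: Evolutionary Analysis of the HES/HEY Transcription-Factor Gene Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative and evolutionary analysis of the HES/HEY
    family of basic helix-loop-helix (bHLH) transcriptional repressors, the
    effectors of Notch signalling. Identifies family members in proteomes by
    their diagnostic dual-domain architecture (bHLH followed by an Orange
    domain) using position-specific scoring matrices with empirical
    permutation significance and greedy redundancy clustering; aligns
    concatenated domain regions and builds neighbor-joining trees with
    resampling support (plus a brute-force minimum-evolution oracle);
    classifies members into the four canonical groups (HEY1/2/L, DEC1/2,
    HESL, HES1-7) by anchored clades; computes exon/intron phase strings
    from gene models and infers minimal exon-loss/intron-loss/intron-gain
    event scripts against the ancestral five-exon 2-0-0-1 structure;
    classifies C-terminal tetrapeptide motifs (WRPW/YRPW/FRPW and degenerate
    variants); detects genomic tandem-duplication clusters; and tests
    teleost-specific expansion with an exact rank-sum test. A synthetic-data
    generator with known truth makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
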