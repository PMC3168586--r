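Package: cnvburden
Title: Hotspot-Targeted Array CGH CNV Calling and Rare-CNV Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects copy number variants (CNVs) from hotspot-targeted array
    comparative genomic hybridization (aCGH) log2-ratio profiles and tests
    for a case-control burden of large rare events. Implements per-chromosome
    z-score normalization, a three-state Gaussian hidden Markov model with
    Viterbi decoding, distance-based segment merging and short-gap bridging,
    size/probe/z-score threshold filters, rarity filtering against control
    CNV catalogs by reciprocal overlap, and an exact (hypergeometric)
    carrier-burden test. Ships a seeded simulator of hotspot-targeted probe
    designs and cohort log2-ratio data with known embedded deletions and
    duplications, plus recovery scoring against the simulated truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
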