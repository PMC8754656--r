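Package: reelscan
Title: Design and Analysis of Iterative EMSA Depletion Screens for Cis-Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fine-mapping cis-regulatory elements (cis-REs) with
    iterative electrophoretic-mobility-shift (EMSA) depletion screens of
    synthetic 35-bp tiling libraries. Designs dual-offset tiling libraries
    over a genomic region, simulates the multi-round gel-shift selection with
    nuclear-extract-treated samples and buffer controls, quantifies fragment
    abundances from exact-matching sequencing reads, calls candidate elements
    from NE/buffer depletion trajectories (per-round t-tests plus a negative
    fitted slope), measures cross-library candidate concordance with a
    chi-squared test, clusters candidates into enhancer-scale windows, scores
    candidate density within annotation intervals, and applies the FREP-MS
    presence/absence rule to peptide spectral-count tables to call specific
    DNA-binding proteins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
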