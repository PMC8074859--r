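Package: repdiv
Title: TCR-Beta Repertoire Diversity, Clonal Expansion and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for T cell receptor beta-chain (TCR-beta) repertoire
    analysis in two-arm patient cohorts: simulation of germline V/J
    references and clonotype repertoires with controllable clonal
    expansion and public-clone sharing, V/J assignment and IMGT-anchored
    CDR3 junction extraction from sequencing contigs via a k-mer seeded
    banded local aligner, per-sample diversity and clonality summaries
    (Shannon entropy, Gini coefficients, highly expanded clones, V-J
    usage), cross-donor public-clonotype sharing, and the cohort
    statistics used to compare persistent versus newly diagnosed
    autoimmune disease groups (Kolmogorov-Smirnov gated Student's t or
    Mann-Whitney U tests, chi-squared tests, Pearson regression of
    diversity against gene expression with Fisher-z confidence
    intervals, and a fold-change/FDR expression screen).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
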