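Package: ringscreen
Title: Genome-Wide Screening for Membrane-Bound RING-Finger Ubiquitin Ligases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico screen for candidate endoplasmic-reticulum-associated
    degradation (ERAD) ubiquitin ligases. Enumerates canonical RING-finger
    motifs (C3H2C3 and C3HC4 subtypes) in protein sequences with a
    variable-gap pattern matcher, counts transmembrane helices either from
    TMHMM-style predictions or a built-in Kyte-Doolittle hydropathy predictor,
    scans transcription-start-site-relative upstream DNA for ER-stress
    cis-elements (ERSE-I, ERSE-II, UPRE) on both strands, and combines the
    stages into candidate tables with summary statistics. Also implements the
    downstream qPCR expression analyses: delta-delta-Ct fold changes, a tau
    tissue-specificity index, ER-stress responsiveness calls by ANOVA with
    Bonferroni-corrected comparisons, and crystal-violet viability ratios.
    Ships a self-verifying synthetic-data generator (planted motifs, planted
    transmembrane stretches, planted promoter elements, Ct tables with known
    fold effects) so the whole pipeline is testable without database
    downloads.
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
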