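Package: splicerescue
Title: Quantification of Splicing and Expression Rescue in Myotonic Dystrophy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how far a therapeutic compound moves
    dysregulated alternative splicing and gene expression back toward
    unaffected levels, as used in transcriptome-wide screens of myotonic
    dystrophy type 1 (DM1) cell models. Implements percent-spliced-in (PSI)
    and percent-rescue statistics with Rescue/Mis-Rescue/No-change
    categorization, a post-processing pipeline for rMATS-style skipped-exon
    (JCEC) tables (canonical event identifiers, cross-contrast matching,
    missing-value and variability filters, dysregulation and off-target
    calls), dose-response summarization with an ANOVA/Dunnett significance
    gate and Hill-model EC50/ECmax estimation, delta-delta-Ct qPCR
    quantification, fluorescence indicator displacement (%FID), and a
    synthetic-data generator with planted ground truth for validating every
    step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    limma,
    minpack.lm,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
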