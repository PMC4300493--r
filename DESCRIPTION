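Package: riboflow
Title: Codon Dwell Times, Protein Synthesis Rates and Translation
    Efficiency from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of ribosome profiling (ribo-seq) data
    under a steady-state flow-conservation model of translation. Infers
    per-gene per-codon ribosome dwell times softly tied to global codon
    dwell times, protein synthesis rates (fluxes) and translation
    efficiency; detects positions of slower-than-expected elongation
    (pausing outliers) and evaluates candidate explanatory features;
    fits an elastic-net translation-efficiency regression with a
    learnable sigmoid Kozak-context feature and exports the learned
    motif as a position weight matrix; and provides DMS
    structure-probing normalisation with sliding-window
    energy/efficiency correlation analyses. A synthetic-data generator
    with known ground truth supports parameter-recovery testing of
    every component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
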