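Package: phytonet
Title: Network Pharmacology and Bioactivity Analytics for Essential Oils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterizing an essential
    oil's chemical composition and multi-target pharmacological profile.
    Covers Kovats/van den Dool retention-index calibration and GC/MS
    composition summaries, Lipinski rule-of-five drug-likeness screening,
    target-overlap network pharmacology with from-scratch degree,
    betweenness and closeness centralities and a two-tier median hub
    screen, hypergeometric over-representation statistics with
    Benjamini-Hochberg control, four-parameter logistic dose-response
    fitting with IC50/CC50 and selectivity-index analytics, Annexin V/PI
    quadrant and cell-cycle quantification, and docking-score
    summarization. Seeded synthetic-data generators with known ground
    truth make every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
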