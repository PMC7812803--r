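Package: gcmyc
Title: Agent-Based Simulation of Permissive Positive Selection in Germinal Centers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based model of the germinal center (GC) reaction in which
    positively selected light-zone B cells acquire cMyc and progress through a
    chain of cMyc+ subpopulations (early, prePB, lateCD23int, lateCD23lo, DZ)
    before recycling to the dark zone or leaving the GC as output. The package
    couples the simulator to in-silico cytometry instruments (EdU/BrdU dual
    pulse labeling, DNA content, phospho-histone H3, CellTrace division
    tracking), a shape-space affinity model with high/low-affinity gating, a
    model-selection harness (normalization, residual sum of squares, corrected
    Akaike information criterion, replicate statistics), and generators of
    synthetic flow-census data anchored to published day-7 reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
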