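Package: colonyfit
Title: Colony-Level Fitness Analysis of Boom-and-Bust Nematode Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying colony-level fitness of Caenorhabditis elegans
    growing on a finite food patch. Implements a deterministic stage-structured
    matrix population model of colony growth (hourly age-class projection,
    food accounting against a fixed patch, post-hoc bust detection, and
    founder-number sweeps), population-structure summaries at bust (dominant
    L1 generation, pre-dauer pool, futile-consumption share), and an analysis
    pipeline for colony fitness assays (dauer-count scaling, group summaries,
    ANOVA with Tukey multiple comparisons, yield time courses, dauer-length
    recovery checks, bacterial-lawn quality control, and the speed-versus-yield
    trade-off table). A seeded synthetic-data generator emulates the plate-level
    structure of the assay data so the whole pipeline can be exercised without
    access to the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
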