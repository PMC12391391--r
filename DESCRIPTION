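Package: gwlpheno
Title: Phenotypic and Molecular Profiling of Cellular Responses to
    Greatwall Kinase Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying cellular
    responses to chemical inhibition of Greatwall (GWL/MASTL) kinase.
    Provides high-content cell-cycle phenotyping from per-cell DNA, EdU
    and p21 intensities (first-peak normalisation, ploidy gating,
    population summaries), a Euclidean/AUC phenotypic drug-response
    statistic, an embedding plus Wasserstein-distance phenotypic
    similarity test for off-target assessment, replicate-wise
    four-parameter log-logistic dose-response fitting with ED50
    estimation, a GWL/B55-alpha expression-ratio model that predicts
    drug sensitivity in cell-line panels and tumour cohorts, and
    moderated differential statistics for phosphoproteomics, together
    with seeded synthetic-data generators carrying ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
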