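Package: foldstab
Title: Stability Analysis and Family Energy Models for Deep Mutational
    Scans of Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for growth-rate-based deep mutational
    scanning of protein domains: per-domain quality control and fitness
    normalization, destabilization calling and clinical-variant
    classification, functional-site identification by sigmoid decomposition
    of stability against evolutionary fitness, two-state Boltzmann energy
    models fitted jointly across homologous domain families with
    cross-validation and prediction for unseen homologues, and epistasis
    detection from model residuals. Includes a synthetic-data generator
    with planted ground truth for end-to-end validation.
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
    jsonlite,
    Matrix,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
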