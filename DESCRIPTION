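Package: dtaforge
Title: Curation, Splitting, Training and Evaluation of Drug-Target Affinity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building drug-target binding affinity (DTA) regression
    models from noisy public bioassay databases. Provides a curation engine that
    filters BindingDB-style measurement tables, resolves threshold-censored
    values by the serial-dilution rule, assigns reliability weights and
    aggregates replicate measurements by a weighted 80th percentile; leakage-free
    cold-target and Bemis-Murcko scaffold train/test splits; cached token-level
    embedding providers for ligands and proteins; a transformer encoder-decoder
    network with a masked weighted multitask loss, RAdam optimization and K-fold
    ensembling; regression metrics (MSE, RMSE, concordance index, Spearman) with
    confidence intervals; and a consensus modeling score aggregating docking,
    MM-GBSA and quantum-chemistry outputs. A synthetic-data module generates all
    supported table dialects with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    stringr,
    readr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
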