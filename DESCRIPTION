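Package: virosig
Title: Gut Virome Case-Control Signature Discovery and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for case-control association analysis
    of the human gut virome across paired virus-like-particle (VLP) and bulk
    metagenomic datasets. Implements evidence-based viral contig triage,
    species-level vOTU clustering (95% average nucleotide identity over 70%
    coverage), trimmed-depth relative-abundance profiling with classified-read
    confirmation, family-level taxonomic voting and CRISPR-spacer host
    prediction, alpha/beta diversity statistics (Shannon, Bray-Curtis, PCoA,
    PERMANOVA), dual-modality Wilcoxon/Benjamini-Hochberg signature calling
    with cross-dataset concordance testing, and random-forest validation with
    repeated cross-validation, cross-dataset and leave-one-dataset-out AUC.
    Ships a seeded synthetic-cohort generator with planted disease signatures
    for end-to-end calibration of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    jsonlite,
    vegan,
    ape,
    randomForest,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
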