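Package: dockconsensus
Title: Consensus Rescoring, Threshold Classification and Interaction
    Fingerprints for Cross-Docking Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-docking analysis toolkit for small-molecule triage across
    multiple scoring functions and docking programs. Provides direction-aware
    relative ranking of docking scores, Borda-count aggregated ranks and
    exponential consensus ranks (ECR), kernel-density-intersection thresholds
    for binder versus nonbinder classification with Matthews correlation and
    balanced accuracy, consensus protein-ligand interaction fingerprints built
    by intersecting PLIP contact records from two docking programs, Tanimoto
    similarity and hierarchical clustering of binding modes, and rank or
    linear correlation of scores against experimental pIC50 values. A fully
    seeded synthetic-study generator emulates cross-docking campaigns with
    known ground truth so every stage of the pipeline can be validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
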