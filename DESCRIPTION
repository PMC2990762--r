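Package: pfantom
Title: Pfam-Domain-Based Subcellular Localization Prediction and
    Mutual-Rank Co-Expression Analysis for Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a protein subcellular localization predictor from
    experimentally evidenced Gene Ontology annotations and Pfam domain
    assignments. Each Pfam domain gets a per-compartment localization ratio
    (the fraction of its experimentally localized carrier proteins seen in
    that compartment); a query protein is scored per compartment by the
    geometric mean of its domains' ratios and called at the argmax.
    Includes per-compartment sensitivity/specificity and ROC evaluation,
    Mutual-Rank ranked-list ingestion with geometric-mean average MR,
    multi-bait intersection (Venn) analysis with Pfam-group summaries, and
    seeded synthetic-data generators for annotation corpora and ranked
    co-expression lists.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
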