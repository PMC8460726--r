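Package: pescreen
Title: Quantification and Predictive Modeling of Prime-Editing Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for barcode-paired prime-editing screens: demultiplexing of
    amplicon deep-sequencing reads by an embedded 22-nt barcode key,
    classification of editing outcomes (intended edit, unintended edit, indel,
    wild type) against per-pair reference targets, editing-frequency and
    pseudocounted fold-change statistics, a fixed 1,820-feature encoding of
    pegRNA/target pairs (position-dependent and position-independent
    nucleotide composition, nearest-neighbor melting temperatures, GC content,
    self-folding minimum free energy, and an optional on-target score), and a
    model-selection harness over seven learners with grouped cross-validation,
    Spearman evaluation, tree-SHAP attribution, and melting-temperature
    binning. Includes seed-deterministic simulators for library designs,
    screen reads, and fold-change tables with planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    jsonlite,
    glmnet,
    e1071,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
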