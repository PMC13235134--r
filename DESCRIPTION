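Package: maskDRP
Title: Biologically Masked Neural Networks for Multi-Omics Drug Response Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the sensitivity of cancer cell lines to drugs with a feedforward
    neural network whose hidden layers mirror the gene -> protein complex -> pathway ->
    drug hierarchy. Binary mask matrices derived from annotation edge lists restrict
    every weight matrix to biologically annotated connections, Morgan (ECFP) drug
    fingerprints are concatenated at the drug layer, and responses are binarized
    against per-drug maximum screening concentrations. Includes availability-weighted
    multi-omics integration, forward/backward hierarchy pruning, four cross-validation
    protocols (random pair k-fold, leave-one-drug-out, leave-one-cell-line-out,
    leave-one-cancer-type-out), a multi-level feature-importance suite, and a seeded
    synthetic-data generator with a planted response mechanism for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'hierarchy.R'
    'omics.R'
    'drugs.R'
    'network.R'
    'synthetic.R'
    'evaluation.R'
    'interpretability.R'
    'io.R'
    'config.R'
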