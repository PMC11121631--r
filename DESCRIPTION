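Package: scloc
Title: Protein Subcellular Localization Prediction with N-to-1 Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular localization of eukaryotic proteins into
    eight compartment classes from sequence alone, using an ensemble of deep
    N-to-1 convolutional neural networks trained on one-hot or clipped
    MSA-profile encodings. Includes the full dataset-construction protocol
    (length filtering, greedy e-value redundancy reduction, interleaved 3:1:1
    splitting), per-example stochastic gradient descent with periodic
    validation checkpointing, best-checkpoint ensembling, one-vs-rest
    evaluation metrics, and a synthetic motif-signal data generator so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
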