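Package: tcrh
Title: Physicochemical Sequence Features and Leakage-Aware Prediction of
    TCR-Epitope Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Predicts whether a T-cell receptor (represented by its CDR3beta
    sequence) binds a peptide epitope, from whole-sequence physicochemical
    descriptors alone.  Computes 96 descriptors per amino-acid sequence from
    bundled per-residue scale tables (Kidera factors, Z-scales, VHSE, Cruciani
    properties and others, plus charge, isoelectric point, hydrophobic moment,
    instability index and mass indices); builds leakage-aware random,
    epitope-hard, TCR-hard and strict train/test splits; trains a support
    vector machine with radial basis function kernel after feature scaling and
    correlation-based pruning; evaluates with confusion-count metrics and
    rank-statistic ROC AUC; and explains trained models with a model-agnostic
    KernelSHAP implementation.  A synthetic-data generator with a planted
    physicochemical binding rule makes the full pipeline testable at desk
    scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
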