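Package: qsarShift
Title: Cross-Source Evaluation of Bioactivity Classification Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how binary QSAR bioactivity models transfer
    between data domains (for example a public ChEMBL-like source and a
    proprietary in-house source). Curates per-target activity data sets under
    potency thresholding and replicate-conflict rules, computes molecular
    descriptors (circular fingerprints, electrotopological-state vectors,
    loadable embedding tables, physicochemical properties), trains random
    forest, gradient boosting and support vector classifiers under random and
    Butina-cluster nested cross-validation with mode-of-hyperparameter
    selection, evaluates frozen models across domains with InChI leakage
    filtering, quantifies chemical-space divergence (nearest-neighbor Tanimoto
    similarity, 2-D manifold embedding, physicochemical distributions), and
    compiles mixed training sets under target / assay-format / similarity
    strategies. Ships a synthetic two-domain study generator so every stage is
    exercisable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    igraph,
    ranger,
    xgboost,
    e1071,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
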