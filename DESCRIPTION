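Package: qstate
Title: Quaternary State Prediction for Homomers from Pooled Protein
    Language Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the homomeric quaternary state of a protein (the
    number of identical chains in its functional unit) from sequence
    alone.  Per-residue embeddings from a protein language model are
    mean-pooled into fixed-length vectors that feed a shallow multilayer
    perceptron classifier and nearest-neighbour annotation-transfer
    baselines (by sequence identity or embedding cosine similarity).
    Includes curation of QSbio-style annotation tables, homology-aware
    train/hold-out splitting and grouped cross-validation folds, class
    rebalancing by random under-sampling, rank-sum confidence analyses
    of prediction reliability, and family-level quaternary-state
    diversity reports.  A deterministic synthetic-data generator with
    family structure and class-conditional embedding signal makes the
    whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
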