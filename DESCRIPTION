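Package: elisl
Title: Early-Late Integrated Ensembles for Synthetic Lethality Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts synthetic-lethal (SL) gene pairs from heterogeneous
    molecular data sources. Gene pairs are featurized from protein-sequence
    embeddings, protein-protein interaction network embeddings, CRISPR
    gene-dependency screens conditioned on partner alteration status, and
    patient tissue omics (co-mutation survival, conditional expression,
    coexpression and copy-number correlation). Per-source tree ensembles and
    a concatenated-features ensemble are combined by a weighted average with
    validation-performance-normalized weights. Includes selection-bias-robust
    evaluation protocols (pair-disjoint, double gene holdout, cross
    label-source), permutation feature-category importance, and a synthetic
    multi-omics data generator with plantable SL effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    xgboost,
    survival,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
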