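Package: dmwnn
Title: Double Multi-Weighted Nearest Neighbor Prediction of lncRNA-Disease
    Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts long noncoding RNA (lncRNA)-disease associations by
    memory-based matrix completion on a sparse binary adjacency matrix.
    Interaction profiles that concatenate miRNA and disease association
    vectors feed a fused potential-association similarity; a double
    (row- and column-wise) multi-weighted k-nearest-neighbor model with
    linearly decreasing weights fills the unknown entries, and multilayer
    stacking reaches cells no single pass can score. Ships cross-validation
    drivers (k-fold and leave-one-out), ranking and confusion-matrix
    metrics, per-disease candidate ranking, baseline similarities (cosine,
    Pearson, Jaccard), and a generator of coupled synthetic
    lncRNA-miRNA-disease networks with planted low-rank structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
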