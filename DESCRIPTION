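Package: featkit
Title: Feature Representations for CRISPR Guide Activity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encoding strategies for paired gRNA/off-target alignments and single
    guide sequences (positional mismatch matrices, bulge-aware grids, label and
    one-hot encodings, k-mer composition), imbalance-aware preprocessing (count
    thresholds, log transforms, class weighting), guide-grouped cross-validated
    gradient-boosted-tree models for knockout off-target prediction and
    base-editing efficiency screens, precision-recall evaluation machinery for
    heavily imbalanced data, and a TreeSHAP/ALE explainability layer. Includes
    synthetic-data generators emulating the structure of genome-wide off-target
    assays and base-editor viability screens so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xgboost,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
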