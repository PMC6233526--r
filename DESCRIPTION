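Package: cpligand
Title: Ligand-Based Target Profiling with Mondrian Conformal Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds panels of ligand-based binary activity models with valid
    confidence measures. Molecules are described by signature descriptors
    (canonical strings for atom-rooted subgraphs of bounded height) and
    classified per target by Mondrian aggregated conformal predictors over
    linear support vector machines, yielding per-class p-values instead of
    point predictions. Includes the activity-table preparation rules
    (conflict removal, SMILES-level deduplication, target filtering,
    assumed-non-active augmentation, external holdout), efficiency and
    validity metrics (observed fuzziness, class-averaged observed fuzziness,
    multi-label criterion, calibration curves, label-set confusion tables),
    cross-validated cost tuning, a synthetic activity-table generator for
    end-to-end testing, and multi-target profile prediction with atom-level
    contribution scores.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    e1071,
    SparseM,
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
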