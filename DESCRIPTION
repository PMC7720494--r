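Package: nodalratio
Title: Hazard-Weighted Lymph-Node Ratio Staging for Cancer Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive and validate a modified nodal (N) stage for
    esophageal cancer from counts of positive and negative regional lymph
    nodes. The positive- and negative-node counts are weighted by the
    distance of their Cox proportional-hazards ratios from the null value
    of one, combined into a re-adjusted N ratio per patient, and staged by
    cutpoints chosen with a minimum-p-value log-rank scan. Includes a
    synthetic SEER-like cohort generator with known ground-truth per-node
    hazard effects, cohort ingestion with inclusion-criteria filtering,
    first-party Kaplan-Meier and k-group log-rank primitives, train and
    validation cross-validation, ROC comparison against count-based AJCC
    style staging, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
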