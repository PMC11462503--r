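Package: intrisol
Title: Intrinsic Aqueous Solubility Curation and Data-Quality Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates intrinsic aqueous solubility from high-throughput
    pH 2/pH 7 discovery solubility assays using chromatographic log D
    triplets (pH 2.6/7.4/10.5), following a three-step workflow of
    filtering, Henderson-Hasselbalch-guided extraction, and a 3-fold
    pH-consistency quality check. Ships a synthetic assay simulator
    (right-skewed intrinsic solubility, 0.1-600 uM dynamic-range
    censoring, amorphous solid-state bias, replicate analytical
    variability, measured and predicted log D), a factory for six
    dataset variants that isolate label noise, training-set size and
    amorphous bias, a descriptor decorrelation filter, random-forest
    modeling with nested cross-validation, and evaluation experiments
    with ANOVA/Tukey comparison and over/under-prediction bias analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    e1071,
    glmnet,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
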