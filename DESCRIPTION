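Package: vershuffle
Title: Version-Shuffled Brain Age Prediction and Cross-Version Model Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired two-version cortical morphometry tables
    (Desikan-Killiany thickness, surface area and volume as estimated by two
    releases of a surface-reconstruction pipeline), trains age-prediction
    models on single-version and version-shuffled training compositions under
    repeated train/test resampling, and runs the full comparison battery:
    cross-version prediction grids, bagged predictions, tests for overlapping
    dependent correlations (Zou confidence intervals, Hittner Z), marginal-mean
    contrasts, mixed-model site checks, permutation feature importance and
    principal-component structure analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    xgboost,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
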