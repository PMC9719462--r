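Package: cat2eq5d
Title: Mapping COPD Assessment Test Scores to EQ-5D-3L Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for predicting EQ-5D-3L health-state utilities from the
    eight-item COPD Assessment Test (CAT). Implements response mapping via
    per-dimension multinomial logistic models combined with the Taiwanese
    time-trade-off value set, direct ordinary-least-squares mappings,
    two-part (classify-then-regress) mappings, and the nonparametric Mean
    Rank Method, together with the model-development machinery (pooled
    multinomial fitting with cluster-robust covariance for repeated
    measures, backward elimination, QIC model selection) and a validation
    toolkit (MAE/RMSE subgroup reports, calibration bubble-chart data). A
    synthetic repeated-measures cohort generator emulating the statistical
    structure of a Taiwanese COPD clinic population supports end-to-end
    testing without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), nnet, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
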