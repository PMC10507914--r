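Package: thoracoCUA
Title: Trial-Based Cost-Utility Analysis of Thoracoscopic Versus Open
    Thoracic Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Patient-level medico-economic analysis pipeline for a two-arm
    randomised surgical trial: hospital costing by diagnosis-related group
    (DRG) with micro-costing substitution for the operating room
    ('adjusted-DRG' method), EQ-5D-3L utility scoring with pluggable national
    value sets, interval-weighted QALY computation, cost-minimisation and
    cost-utility analyses with non-parametric bootstrap acceptability curves,
    and multiple imputation by chained equations as a sensitivity analysis.
    Includes a calibrated synthetic-trial generator (centre-stratified block
    randomisation, EQ-5D trajectories, hospital-stay events, missingness
    mechanisms) so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
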