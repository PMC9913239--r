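Package: thermodose
Title: Thermal Injury Kinetics and Dosimetry for Hyperthermia Cell Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward models of heat-induced cell death (Arrhenius damage
    integral, time-delayed Arrhenius with a shoulder region, two-state
    logistic survival, and CEM43 thermal isoeffective dose) evaluated on
    arbitrary time-temperature profiles, together with the inverse
    procedures that estimate kinetic coefficients (activation energy,
    frequency factor, shoulder delay, logistic coefficients, R_CEM) from
    in vitro viability data; a synthetic-data generator emulating
    water-bath hyperthermia experiments on 96-well plates; and a pipeline
    that fits all models to a viability dataset and compares them by
    root-mean-square prediction error.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
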