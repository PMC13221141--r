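Package: tdtsurv
Title: Thermal Death Time Survival Models for Ectotherms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits parametric accelerated-failure-time models with
    temperature-linked scale and shape to constant-temperature failure
    (knockdown) time data from thermal-tolerance assays, estimates the
    thermal death time (TDT) regression of log median failure time on
    temperature, and compares candidate failure-time distributions by AIC.
    Predicts median failure times and full survival curves under fluctuating
    stressful temperatures via three models: a deterministic additive-damage
    model, a pooled average-survival-curve model, and an increasing-variance
    log-logistic model in which both the scale and the shape of the failure
    time distribution change with temperature. Includes likelihood-based
    model-comparison statistics, diagnostics for the TDT assumptions, and a
    synthetic-data generator emulating static and dynamic knockdown assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
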