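Package: pigvent
Title: Simulated Porcine Two-Hit Lung Injury and Closed-Loop Protective Ventilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Breath-by-breath simulator of a porcine model of combined
    surfactant-depletion (saline lavage) and ventilator-induced lung injury,
    together with the protocol machinery used to study it: an ARDSNet-style
    closed-loop controller (SpO2-driven PEEP/FiO2 table, PIP-triggered tidal
    volume reduction, pH-driven respiratory rate titration), recruitment
    maneuvers, volume-history standardization, decremental PEEP trials with
    best-PEEP identification by compliance, oxygenation or oxygen delivery,
    simplified pressure-controlled mechanical power, and the nonparametric
    descriptive statistics (relative treatment effects, Mann-Whitney U) used
    to compare protective versus injurious ventilation arms.
License: MIT + file LICENSE
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
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
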