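Package: ibmsens
Title: Sensitivity, Stability and Calibration Analysis for Stochastic
    Individual-Based Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A native toolkit for the systematic analysis of stochastic
    individual-based (agent-based) simulation models: experimental designs
    (random, Latin hypercube, full factorial), Morris elementary-effects
    screening (mu, mu*, sigma), Sobol variance-decomposition sensitivity
    indices (Saltelli/Jansen estimators), replication-count determination by
    coefficient-of-variation convergence, and sampling-based calibration with
    categorical and distance-based objective functions.  Two biological
    simulators are bundled as first-class test subjects: a wolf-sheep-grass
    predator-prey model on a periodic continuous space (with a Lotka-Volterra
    ODE reference) and a nutrient-limited bacterial colony model in which a
    cheater plasmid competes for a shared type IV secretion system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
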