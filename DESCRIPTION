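Package: buildtail
Title: Buildup-Tail Modeling of Photon Depth Dose and Collimator Scatter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and evaluates a two-parameter empirical model of megavoltage
    photon percent-depth-dose (PDD) curves, the product of a quadratic buildup
    term d/(d^2 + n) and an exponential attenuation tail exp(-mu*d), and the
    collimator-scatter-factor (Sc) models derived from it: a per-energy
    power law in square field size and a weighted-jaw power law for
    asymmetric upper/lower collimator settings. Provides nonlinear
    least-squares calibration to water-phantom scan data and measured Sc
    tables, depth-of-maximum location, Table-style measured/modeled
    comparison reports, a synthetic-scan generator with known ground truth
    for recovery testing, and a command-line interface for commissioning QA
    and monitor-unit double-check workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
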