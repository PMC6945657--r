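Package: linactune
Title: Truncated Fine-Tuning of Linac Photon-Beam Parameters via Gamma-Index Trend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for commissioning a Monte-Carlo linac photon-beam model
    against measured water-phantom scans at low statistics. Implements a
    gamma-index comparison engine for percent-depth-dose and lateral profile
    curves (dose-difference / distance-to-agreement, one-fifth-bin resampling,
    bounded candidate search), a Pearson-trend decision rule that selects the
    initial electron-beam energy from passing-rate trends across history
    sweeps, and a three-stage serial grid search over the remaining beam
    parameters (energy spread, focal-spot size, divergence). A parametric
    dose simulator with Monte-Carlo-like noise stands in for a full radiation
    transport code so the whole workflow is self-contained and testable.
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
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
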