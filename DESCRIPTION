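Package: corovalve
Title: Multi-Scale Modelling of Coronary Hemodynamics Under Aortic Valve Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop lumped-parameter (0D) model of the human circulation with
    a time-varying elastance heart, an effective-orifice-area (EOA) parameterized
    aortic valve supporting stenosis (AS) and regurgitation (AR) presets, and a
    three-layer autoregulated coronary circulation driven by layer-graded
    intramyocardial pressure. A distributed coronary-segment model is coupled to
    the closed loop through an explicit partitioned boundary-exchange algorithm,
    and waveform analytics (velocity-time integrals, Fourier harmonics,
    time-averaged wall shear stress and oscillatory shear index) quantify how
    aortic valve disease alters coronary flow. Includes Nelder-Mead calibration of
    systemic parameters to population hemodynamic targets and a linear
    negative-feedback controller that tracks a coronary perfusion pressure-flow
    autoregulation curve.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
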