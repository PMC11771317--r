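Package: thinfil
Title: Near-Neighbor Cooperative Kinetics of Cardiac Thin-Filament Activation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Coupled four-state kinetic model of cardiac thin-filament
    regulation and crossbridge cycling with nearest-neighbor RU-RU, XB-XB and
    XB-RU cooperative interactions under a Bragg-Williams mean-field closure.
    Simulates steady-state force-pCa relations and the slack-restretch rate of
    force redevelopment (ktr), evaluates activation and crossbridge-recruitment
    factors, sweeps cooperative coefficients, fits the model to contractility
    data by constrained multi-start least squares, and generates synthetic
    contractility datasets with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
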