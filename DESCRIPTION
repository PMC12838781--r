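Package: recres
Title: Recurrence Resonance and Attractor Landscapes in Stochastic
    Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for recurrence resonance in
    small stochastic recurrent neural networks. Builds connectivity
    matrices from truncated-normal weight classes under quantum-logic
    (pasted Boolean algebra), diagonal, and broken-background conditions;
    simulates noisy tanh dynamics; detects resonance with plugin entropy,
    temporal mutual information and transfer entropy estimators over
    noise sweeps; characterises attractor landscapes with empirical state
    transition matrices, visitation gain and diagonal stability; and
    constructs rough-set fixed-point lattices with Hasse diagrams and
    distributivity checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
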