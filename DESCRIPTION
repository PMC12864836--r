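Package: cyclecrit
Title: Cell-Cycle Criticality and Stem-Cell Population Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the G1-S transition of the cell cycle as a stochastic
    saddle-node (fold) bifurcation in active Rb, and analyses the
    consequences for stem-cell population control. Provides fixed-point and
    fold analysis of the Rb/E2F switch, exact Airy-function mean
    first-passage (delay) times for the critical normal form together with
    the Kramers approximation and empirical SDE ensembles, an agent-based
    stem-cell homeostasis simulator with competing RD/DR fate topologies,
    mis-sensing mutant invasion and two-compartment feedback, ghost-state
    (critical slowing down) trajectory analysis, condition-level G1-length
    distribution summaries with bifurcation-versus-linear model scoring,
    and a synthetic per-cell G1-length data generator with parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
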