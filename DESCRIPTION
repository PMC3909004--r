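Package: abxtradeoff
Title: Two-Drug Antibiotic Deployment Strategies Under Multidrug
    Resistance Tradeoffs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic five-compartment model of a closed hospital
    population in which patients are treated with two antibiotics under
    alternative deployment strategies (no treatment, single drug, cycling,
    mixing, and combined or separate two-drug cocktails).  Bacterial
    clearance is driven by Hill-type pharmacodynamic growth functions of
    drug concentration, and double resistance is constrained by a
    pleiotropic tradeoff between the two minimal inhibitory
    concentrations.  Provides a fixed-step Runge-Kutta integration engine
    with equilibrium detection and cycle averaging, closed-form
    equilibrium cross-checks, tradeoff sweeps, and bisection of
    dominant-strain switching thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
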