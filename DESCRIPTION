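Package: voltsense
Title: Voltage Sensing by the Allosteric Sodium Ion in Class A GPCRs
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for membrane-voltage sensing by
    the internal sodium ion of class A G-protein-coupled receptors.
    Provides analytic reference free-energy profiles and electrical-distance
    maps for the delta-opioid receptor (wild type and Asn131(3.35)Val
    mutant) and the M2 muscarinic receptor, an overdamped Langevin sampler
    on one-dimensional potentials, umbrella sampling with WHAM
    reconstruction and Bayesian-bootstrap errors, transmembrane-voltage
    determination from charge-density profiles by double integration of
    Poisson's equation, gating-charge estimation from charge-imbalance
    versus voltage relationships, voltage-tilted non-equilibrium energy
    landscapes with mean-first-passage-time kinetics, and trajectory
    state/transition analysis.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
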