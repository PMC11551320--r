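Package: confex
Title: Multi-State Conformational Exchange Analysis from NMR Peak Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the conformational landscape of slowly interconverting
    (fold-switching) proteins from three classes of NMR observables: real-time
    HSQC peak-intensity kinetics after a temperature jump, chemical exchange
    saturation transfer (CEST) profiles, and Carr-Purcell-Meiboom-Gill (CPMG)
    relaxation dispersion. Provides Bloch-McConnell forward models for
    multi-state exchange, a seeded synthetic-data generator, global exponential
    fitting with bootstrap uncertainty, two- and three-state CEST model fitting
    with reduced chi-squared model comparison, CPMG Rex estimation with a
    two-temperature regime classification, Eyring free-energy landscape
    construction, and chemical-shift comparison utilities for discriminating
    structural models of minor states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
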