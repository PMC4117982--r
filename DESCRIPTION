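Package: axonwave
Title: Compartmental Simulation of Conduction in Dysmyelinated Auditory Nerve Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Biophysical simulation of action-potential conduction along the
    myelinated central axon of auditory-nerve fibres. Builds periodic
    node-of-Ranvier / internode cable geometries for a control axon and for two
    acoustic-overexposure (AOE) dysmyelination scenarios, attaches
    Hodgkin-Huxley style sodium (Nav), high-threshold (Kv3.1) and low-threshold
    (Kv1.1) potassium conductances, and integrates the multicompartment cable
    equation with an implicit backward-Euler scheme and exponential gating
    updates. Protocol functions reproduce the conduction-velocity measurement,
    internode-length and dysmyelination-extent sweeps, sodium-conductance
    block-threshold search, firing-rate curves and nodal leak-current
    recordings, returning tidy tibbles ready for dplyr and ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
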