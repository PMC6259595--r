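Package: ionflux
Title: Thermodynamic Models of Passive and Active Transmembrane Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A general thermodynamic formulation for transmembrane transport of
    ions and uncharged solutes. Computes Gibbs-energy budgets, forward/backward
    rates, flux and electrogenic current for arbitrary single- or multi-species
    transport mechanisms (channels, ATPases, exchangers, symporters) with an
    asymmetric-flow (rectification) bias. Includes the approximation ladder
    connecting the general current to conductance-based, Goldman-Hodgkin-Katz,
    hyperbolic-sine and rectifier-limit forms; least-squares fitting of
    current-voltage relationships with a classed model object; and two fully
    parameterised membrane-potential models (a cardiac sinoatrial-node
    pacemaker and a striatal fast-spiking interneuron) with spike-train
    analysis utilities (period, amplitude, maximal depolarisation rate,
    rheobase).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
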