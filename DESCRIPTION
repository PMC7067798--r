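Package: filosyn
Title: Stochastic Models of Filopodial Kinetics and Synapse Formation in
    Developing Axon Terminals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling how filopodial dynamics control synapse
    formation in developing Drosophila R7 photoreceptor axon terminals.
    Implements a time-inhomogeneous Markov jump ("developmental") model of
    short- and long-lived filopodia, transient and synaptogenic bulbous
    tips, and synapses, simulated exactly by a thinning stochastic
    simulation algorithm; the fast-timescale bulbous-tip inference built on
    the truncated two-dimensional generator matrix over (sB, synB) counts,
    its zero-eigenvalue stationary distribution and Kullback-Leibler
    fitting of (c5, B50, r3); lifetime and Poisson-count estimators that
    assemble complete genotype parameter sets; a mechanistic
    winner-takes-all model of filopodia competing for a conserved pool of
    synaptic seeding factors; and seeded synthetic-data generators that
    emulate live-imaging track tables and count snapshots so the whole
    estimation pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
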