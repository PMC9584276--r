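Package: evoepi
Title: Epidemic Spreading with Evolving Pathogens on Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic, event-driven SIR and SIS epidemics on contact
    networks in which the pathogen evolves as it spreads. Intra-host
    mutation/selection on a strain chain is reduced to an effective random
    walk of the inter-host transmissibility fitness, taken per transmission.
    Provides the microscopic intra-host engine (replicator-mutator dynamics,
    transmission sampling, effective mutation-rate estimation), closed-form
    early-time theory (critical fitness, critical mutation timescale, phase
    boundaries between the infection-free, mutation-driven and volatile
    regimes), orchestration of phase-diagram, explosive-transition,
    mitigation-timing and hysteresis experiments, and an immunity-evasion
    reinfection model with a staged COVID-19-like disease cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
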