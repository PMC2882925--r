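Package: colonysim
Title: Deterministic Cellular-Automaton Simulation of Bacterial Colony
    Morphogenesis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the cross-section ontogeny of bacterial colonies as a
    one-dimensional continuous cellular automaton driven by two signals: a
    substrate-diffusible quorum factor produced by growing and early-stationary
    cells, and a volatile odor factor produced by mature cells and shared
    globally across the dish.  The automaton reproduces finite colony growth
    and the emergence of rimmed (navel / interstitial ring / peripheral rim),
    rimless, confluent and macula phenotypes from a handful of production,
    diffusion and sensitivity parameters.  Includes inoculum-geometry
    builders, zone segmentation and phenotype classification of thickness
    profiles, a threshold-tuning grid search, scripted encounter and
    inoculum-size scenarios, plain-text configuration and trace serialization,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
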