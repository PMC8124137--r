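Package: nhejsim
Title: Mechanistic Simulation of Fast and Slow NHEJ Double-Strand-Break Repair
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Agent-based Monte Carlo simulation of non-homologous end joining
    (NHEJ) repair of radiation-induced DNA double-strand breaks in G0/G1 cells.
    Individual break ends diffuse through the nucleus by a continuous-time
    random walk and progress through protein-loading states by exponential-race
    kinetics. Two pathway topologies are provided: a "parallel" model in which
    the resection-dependent (slow) and resection-independent (fast) branches are
    fully separated, and an "entwined" model in which ends from either branch
    may join in synapsis. Includes synthetic damage generators (photon and
    track-like), a minimal Standard DNA Damage (SDD) text dialect,
    protein-knockout and chromatin-gating variants, recruitment and repair
    kinetics curves, and reduced chi-square comparison against experimental
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, yaml, knitr, rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
RoxygenNote: 7.3.3
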