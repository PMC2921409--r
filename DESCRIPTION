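Package: rulekmc
Title: Network-Free Kinetic Monte Carlo Simulation of Rule-Based
    Biochemical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates rule-based models of protein-protein interaction
    systems written in a subset of the BioNetGen language (BNGL) without
    ever enumerating the implied reaction network.  Chemical species are
    tracked as individual site-graph instances; reaction rules are
    classified into five classes (state change, dissociation, bimolecular
    association, monogamous and non-monogamous ring closure) whose
    cumulative rates are computed exactly, with over-counting corrections,
    and maintained incrementally as events fire.  Events are selected by a
    rejection-free Gillespie-style procedure, so every step executes a
    real reaction.  A generate-first reference oracle (exhaustive network
    expansion, direct stochastic simulation, and mass-action ODE
    integration) is included for validation, together with programmatic
    builders for benchmark models such as trivalent-ligand
    bivalent-receptor aggregation, multisite phosphorylation, and stiff
    two-timescale kinetics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
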