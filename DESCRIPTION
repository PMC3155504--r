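Package: relapsim
Title: Stochastic Effector-Regulatory T Cell Cross-Regulation Model of
    Relapsing Autoimmunity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a prey-predator style model of the
    adaptive immune system in which effector T cells (Teff) and regulatory
    T cells (Treg) cross-regulate each other through Hill functions and are
    forced by stochastic pulse trains of newly produced resting cells.
    Provides fixed-step integration of the six-variable T-cell plus tissue
    damage system, healthy and autoimmune regime presets, a reduced
    two-variable deterministic model with equilibrium and phase-plane
    analysis, parameter sensitivity sweeps with seed-convergence checking,
    perturbation (immunotherapy) experiments, a sliding-window correlation
    pipeline comparing simulated reversible tissue damage with monthly
    contrast-enhancing-lesion counts, and a synthetic patient-cohort
    generator emulating that clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
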