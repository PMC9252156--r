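Package: xpcsre
Title: Reverse Engineering of Two-Time Correlation Functions for
    Non-Equilibrium XPCS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for X-ray photon correlation
    spectroscopy (XPCS) studies of non-equilibrium dynamics such as protein
    liquid-liquid phase separation. Integrates a rescaled two-dimensional
    Cahn-Hilliard phase-field model with temperature-jump quench, provides a
    particle-based heuristic simulator of phase domains (growth, dissolution,
    shape and concentration schedules, Brownian motion), synthesizes coherent
    scattering speckle series as the squared magnitude of the Fourier
    transform of concentration fluctuations, computes two-time correlation
    functions (TTC) over momentum-transfer rings, and quantifies the TTC
    features that encode the kinetics: diagonal modulation, off-diagonal
    tails and the characteristic length they imply via the integer-multiple
    rule, square (frozen-in) features from two-step growth-dissolution
    processes, and noise-driven contrast fluctuations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'ch-solver.R'
    'particle-sim.R'
    'scenarios.R'
    'scattering.R'
    'correlation.R'
    'features.R'
    'io.R'
    'pipeline.R'
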