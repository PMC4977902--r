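Package: cpmsim
Title: Cellular Potts Model Simulation of Tumor Growth on a 2D Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates tumor growth with a two-dimensional Cellular Potts
    (Glazier-Graner-Hogeweg) model. Lattice sites carry integer spins that
    group into dark (tumor) cells, light (normal) cells and extracellular
    matrix; Metropolis spin-copy dynamics minimise a Hamiltonian combining
    differential-adhesion boundary energies and an area-elasticity
    constraint. Provides seeded, reproducible simulation runs, per-step
    growth trajectories, Gompertz growth-curve fitting, named parameter
    presets, and exporters for CSV trajectories, graph-elements JSON and
    PNG lattice snapshots, plus a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
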