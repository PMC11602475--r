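Package: oxbilayer
Title: Structural and Dynamic Analysis of Native and Oxidized Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing molecular-dynamics models of erythrocyte
    plasma-membrane patches in their native and ferroptosis-oxidized
    (hydroperoxide-substituted) states. Builds per-leaflet lipid compositions
    and derives hydroperoxide-substituted counterparts; reads and writes
    GRO/PDB coordinates, DCD trajectories and GROMACS pull-style umbrella
    time series; computes mass-density profiles, bilayer thickness, area per
    lipid, deuterium order parameters, acyl-tail geometry angles, geometric
    hydrogen bonds, lateral diffusion coefficients from mean-square
    displacement, WHAM free-energy profiles from umbrella sampling,
    position-dependent diffusion from force autocorrelation, and
    solubility-diffusion membrane permeability. Ships seeded synthetic-data
    generators with known ground truth so every stage is testable without
    molecular-dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
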