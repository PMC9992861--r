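Package: motorscape
Title: Conformational and Energetic Analysis of Molecular-Motor Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterize conformational ensembles of actomyosin
    and other molecular-motor complexes from multi-model PDB files.
    Computes per-frame collective variables (atom-pair distances,
    actin-binding cleft width, helix/strand crossing angles, buried
    contact areas, superposition RMSD), recovers equilibrium free-energy
    profiles from Gaussian-accelerated MD (GaMD) boost potentials via
    cumulant-expansion reweighting, detects and labels energy basins,
    clusters ensembles with the GROMOS leader algorithm, and summarises
    one-dimensional distributions (most-probable values, secondary
    peaks). A synthetic-data module generates toy motor ensembles with
    planted collective-variable values and boosted samples from known
    potentials so every analysis stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
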