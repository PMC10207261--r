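Package: orstab
Title: Stability Validation of Predicted Olfactory Receptor Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular-dynamics-based validation of machine-learning-predicted
    G-protein coupled receptor structures, with the human olfactory receptor
    use case in mind. Compares candidate models by mutual backbone RMSD with a
    classical multidimensional scaling projection, quantifies fold stability
    along trajectories (heavy-atom RMSD, TM6-TM7 helix spacing, an activation
    index over interhelical C-alpha distances, sodium-site occupancy near
    D2.50/E3.39), detects complete water permeation events through the
    receptor interior under periodic boundary conditions, performs gromos
    conformational clustering on mutual RMSD matrices, compares helix-helix
    contact interfaces, and counts residue conservation at
    Ballesteros-Weinstein positions. A synthetic trajectory generator builds
    idealized seven-helix transmembrane bundles with scripted helix splaying,
    planted permeation events and ion-binding schedules, providing ground
    truth for end-to-end validation of the whole protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    Biostrings,
    yaml
Config/testthat/edition: 3
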