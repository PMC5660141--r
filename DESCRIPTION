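Package: zdisktomo
Title: Cryo-Electron Tomography Pipeline for the Insect Flight-Muscle Z-Disk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for cryo-electron tomography of
    the hexagonally ordered insect flight-muscle Z-disk. Generates a parametric
    Z-disk phantom with exact p321 two-sided plane-group symmetry (oblique
    antiparallel F-actin trimers with alpha-actinin-like cross-links),
    simulates single-axis Saxton-scheme tilt series with cumulative radiation
    damage, performs marker-free tilt-series alignment against reprojections,
    weighted back-projection, reciprocal-lattice subvolume picking, alignment
    by classification, sixfold crystallographic symmetry expansion with
    missing-cone compensation, and resolution assessment by Fourier shell
    correlation, together with structural measurements (channel rotation,
    disk thickness and filament overlap).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
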