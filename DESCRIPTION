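Package: smlmpipe
Title: Post-Processing and Spatial Statistics for Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for two-color single-molecule
    localization microscopy (dSTORM) of membrane receptors. Reads and writes
    ThunderSTORM-style localization tables; applies the standard
    post-processing chain (duplicate removal, uncertainty and density
    filtering, fiducial-based drift correction, blink merging) and
    polynomial channel registration; quantifies nanoscale clustering with
    the Hopkins index, Ripley's K/L/H functions, DBSCAN cluster density and
    a Getis-type local statistic; measures two-color association with
    coordinate-based colocalization (CBC); and estimates membrane diffusion
    coefficients from single-particle tracking via mean squared
    displacement. A synthetic-data module generates ground-truth emitter
    fields (Thomas cluster process), blinking localization tables with
    drift, fiducials and channel misalignment, and Brownian trajectories,
    so the whole pipeline is testable without raw image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
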