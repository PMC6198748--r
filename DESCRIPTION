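Package: fibrilmech
Title: Single Collagen Fibril Nanomechanics and Post-Rupture Structural Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bowstring tensile tests of single collagen
    fibrils and their post-rupture structural characterization. Converts AFM
    cantilever geometry and vertical calibration into lateral spring constants
    and sensitivities, turns lateral-force and video midpoint-deflection traces
    into stress-strain curves and mechanical parameters (rupture strain and
    stress, toughness, high-strain modulus), measures fibril cross-sectional
    area, D-band periodicity, kink spacing and height loss from AFM height maps,
    extracts the second-order susceptibility anisotropy parameter from
    polarization-resolved second-harmonic-generation image stacks by Fourier
    decomposition, and calls collagen-hybridizing-peptide fluorescence
    positivity. A seeded synthetic-data generator emulates every input modality
    with known ground truth so each stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    pracma,
    stats,
    tiff,
    utils,
    yaml,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
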