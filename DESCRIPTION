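Package: acquant
Title: Quantification of Anchor-Cell Positioning, Invasion and Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-quantification toolkit for fluorescence time-lapse studies of
    anchor-cell (AC) behaviour during Caenorhabditis elegans vulval
    morphogenesis. Provides a ground-truthed synthetic two-channel microscopy
    generator (ellipsoidal AC body with a ventral invasive protrusion, a
    basement-membrane sheet with a breach, punctate junction landmarks, PSF
    blur and camera noise), Richardson-Lucy deconvolution and translation
    registration, landmark-based alignment metrics (the alignment ratio R_A and
    the AC-to-mid-vulF distance Delta), dorsoventral polarity index,
    basement-membrane surface extraction with breach detection, voxel-counting
    protrusion volumetry, a frame-to-frame correlation index of AC shape
    dynamics (C_I), long-term morphometry (vulA distance, lumen-expansion
    delay, actin-ring occupancy scoring), and the cohort statistics layer
    (vulval induction index, Wilson proportion intervals, Welch t, Mann-Whitney
    U, F-test for variance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
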