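Package: fibsemtools
Title: Alignment, Charge-Artifact Suppression and Resolution Estimation
    for Serial FIB/SEM Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Headless processing tools for cryogenic serial focused ion
    beam / scanning electron microscopy (FIB/SEM) image stacks: slice-to-slice
    registration with a physically constrained affine transformation family
    fitted to landmark matches (avoiding nonphysical rotations), row-wise
    suppression of charging-artifact tails by shifted logistic sigmoid
    fitting around labelled charging centres, and image resolution
    estimation by Fourier ring correlation, including the calibrated
    one-image (checkerboard subsampling) variant and tiled local resolution
    maps.  A seeded synthetic-data module generates textured SEM-like
    slices, charging fixtures and band-limited image pairs with known
    ground truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
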