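Package: texphan
Title: Digital Texture Phantoms and Repeatability Analysis for MR Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an end-to-end MR radiomics robustness study on digital
    texture phantoms. Generates ground-truth voxel phantoms (an extruded QR-code
    cube, a level-2 3D Hilbert-curve cube, and procedural fruit/vegetable
    look-alikes), images them with a virtual MR scanner across a factorial
    acquisition matrix (field strength, weighting, coil, voxel size) with
    partial-volume blur, bias fields, repositioning and Rician noise, and
    extracts 45 IBSI-style texture and histogram features after mu +/- 3 sigma
    normalization and fixed-bin-size or fixed-bin-number discretization.
    Repeatability and reliability are quantified with the coefficient of
    variation, relative percentage differences, two-way ANOVA intraclass
    correlation coefficients, and a QR-code readability metric backed by a
    built-in ISO/IEC 18004 encoder and decoder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    rlang,
    RNifti,
    png,
    tibble,
    dplyr,
    tidyr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
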