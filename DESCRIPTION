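Package: filapick
Title: Automated Filament Picking for Cryo-EM Helical Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts start-end coordinates of amyloid and other helical
    filaments from the per-pixel score maps of a sliding-window particle
    scorer, in four steps: binarization, skeletonization, probabilistic
    Hough line detection, and merging of near-collinear segments.
    Includes the helical bookkeeping arithmetic used in amyloid
    processing (twist from crossover distance, inter-particle spacing,
    down-scaled pixel size, pixel-size miscalibration correction),
    Relion-compatible STAR coordinate output with orientational priors,
    MRC image input/output, and a synthetic-micrograph simulator with a
    surrogate ridge scorer for end-to-end testing against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
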