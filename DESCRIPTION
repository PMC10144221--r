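Package: printability
Title: Printing Accuracy and Process Analytics for Extrusion Bioprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized analytics for extrusion-based bioprinting.
    Fits the Ostwald-de Waele (power-law) model to rheometer viscosity
    curves and plans pneumatic extrusion pressure through a cylindrical
    nozzle via the power-law Hagen-Poiseuille relation. Quantifies the
    printing accuracy of single-layer line, circle and angle structures
    from calibrated photographs (local-threshold binarization, connected
    component segmentation, sub-pixel boundary tracing, normalized width,
    length, radii and angle metrics). Gates flow-cytometry live/dead
    events and computes cell viability. Ships a synthetic-data generator
    that renders ground-truthed structure images, viscosity curves and
    cytometry event mixtures for end-to-end validation, plus replicate
    aggregation with first-order (Taylor) uncertainty propagation,
    Jarque-Bera normality checks and one-way ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
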