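Package: cellpolarity
Title: Single-Cell Polarity, Morphology and Junction Feature Extraction with
    Circular Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts per-cell polarity, morphology, intensity and junction
    features from multi-channel 2D fluorescence microscopy images with
    instance segmentation masks, and summarises collective cell behaviour
    with circular statistics. Features include image-moment shape
    orientation and elongation, directed front-rear polarity angles
    (nucleus-Golgi, nucleus displacement, marker polarity), cue directional
    intensity ratios, compartmentalised intensity readouts, and junction
    morphometrics from dilated cell outlines. The statistics layer provides
    the polarity index (mean resultant length), the signed polarity index,
    circular confidence intervals, uniformity tests (Rayleigh, V, Watson,
    Rao spacing), circular-linear and circular-circular correlation, and
    bootstrap-coupled estimation of group differences. A synthetic monolayer
    generator with full ground truth supports end-to-end validation by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
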