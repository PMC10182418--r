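Package: rodsize
Title: Slice-Based Geometry Quantification and Steady-State Size Laws for
    Rod-Shaped Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies single-cell length, width, surface area and volume
    from two-dimensional cell contours by discretising each cell into
    segments perpendicular to its long axis and assuming rotational
    symmetry per segment, as used for fission-yeast morphometrics. Includes
    a synthetic-data generator for rod-cell shapes, masks and
    pseudo-brightfield/septum-marker images with analytic ground truth;
    contour extraction and automated septum-based selection of dividing
    cells; simulation of steady-state turbidostat culture panels across
    growth-rate modulations; and the statistical layer for size-law
    analysis (exponential growth-rate fits from optical-density regrowth,
    per-culture averaging, linear metric-versus-growth-rate fits with 95
    percent confidence intervals, shared-line collapse tests, and
    surface-to-volume trend classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
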