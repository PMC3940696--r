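Package: hsvstain
Title: Quantification of Histological Stains by HSV Color-Space Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies positively stained tissue area in histological section
    images by thresholding in the hue-saturation-value (HSV) color space.
    Converts 8-bit RGB rasters to HSV with hexcone formulas scaled to
    H in [0,360] and S, V in [0,255], classifies pixels with up to three
    axis-aligned threshold cuboids (with hue-wrap support), reports pixel
    counts and percent of a region of interest, renders recolored overlays
    and color-space density maps, and ships a ground-truthed synthetic
    stained-section generator with thickness, fold, defocus and downsampling
    perturbations for robustness experiments against an RGB baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
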