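Package: histoquant
Title: Whole-Section Immunofluorescence Quantification and Segmentation Validation
Version: 0.1.0
Authors@R: person("Histoquant", "Developers", role = c("aut", "cre"),
    email = "maintainers@histoquant.invalid")
Description: A toolkit for quantitative analysis of single-channel
    immunofluorescence images of whole tissue sections (kidney
    cortex + outer stripe of the outer medulla being the motivating
    compartment). Provides calibrated image, mask, outline and point-set
    I/O; rolling-ball background subtraction; histogram auto-thresholding
    (IsoData-variant, Otsu, Triangle, Mean, Li) in whole-section or
    per-ROI mode; a random-forest pixel classifier on an ilastik-style
    filter bank; nucleus detection via hole filling, distance-transform
    watershed and particle-area filtering; segmentation validation with
    pixel confusion metrics and one-to-one point matching (Dice,
    sensitivity, specificity); region-restricted quantification (area
    fraction, detections per square millimetre, intersection over union);
    spatial heterogeneity analysis with circular-kernel density heatmaps,
    hexagonal close-packed circular ROI tiling and Pearson correlation of
    paired stain densities; and a seeded synthetic-section generator with
    full ground truth for testing every stage without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    sp,
    tools,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
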