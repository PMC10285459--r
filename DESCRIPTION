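Package: rotodet
Title: Rotated-Box Detection Toolkit for Slender Crop-Damage Symptoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting elongated, arbitrarily oriented crop-damage
    symptoms (such as the white feeding scars left by rice leaffolder larvae)
    in field imagery using rotated bounding boxes. Provides rotated-box
    geometry in the long-edge convention (skew intersection-over-union and
    intersection-over-foreground by convex polygon dissection, rotated
    non-maximum suppression), readers and writers for the roLabelImg and
    labelImg XML annotation dialects, a synthetic field-scene generator that
    emulates the statistical structure of rice-canopy damage datasets,
    pyramid anchor generation with adaptive positive-sample selection,
    delta box coding and detection losses, rotated region-of-interest
    alignment, a compact two-stage rotated detector trainable on the CPU,
    and average-precision evaluation for oriented detections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
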