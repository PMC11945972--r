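Package: pupilloc
Title: Real-Time Pupil Center Localization in Blurred Near-Infrared Eye Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates the pupil center in near-infrared periocular images that may be
    strongly defocus-blurred, using a double-constraint pipeline: a grayscale
    constraint extracts a rough pupil region (histogram-valley adaptive threshold,
    binarization, gray integral projection, expanded rectangular mask); a geometric
    constraint refines it (8-connected components, morphological opening, hole
    filling, and a pupil shape index combining the region's inertia ratio with an
    ellipse-fitting error); and geometric moments deliver a sub-pixel center and an
    equivalent-circle radius. Includes a ground-truthed synthetic eye-image
    generator with controllable defocus blur, an evaluation harness (Euclidean
    localization error and thresholded accuracy, stratified by blur level), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
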