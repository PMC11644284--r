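Package: tillerqtl
Title: Image-Based Tiller Angle Phenotyping and Dynamic QTL Mapping for Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable re-implementation of an image-based
    rice phenotyping and dynamic QTL analysis workflow. The package renders
    synthetic side-view images of potted rice plants with known tiller angles,
    segments plants from the background by thresholding CIE L*a*b* and HSI
    color channels followed by median filtering and morphological repair,
    extracts six silhouette shape descriptors (projected area, convex hull
    area, compactness, eccentricity, and bounding-box extents), and measures
    the maximum tiller angle from the basal region of the binary mask. On the
    genetics side it simulates recombinant inbred line (RIL) populations under
    the Kosambi map function, performs composite interval mapping (CIM) by
    Haley-Knott regression with permutation-based LOD thresholds, maps both
    stage-wise (unconditional) traits and between-stage increments
    (conditional delta-T traits), and calls, names, and classifies QTL peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
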