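Package: oratex
Title: Texture-Based Screening of Anomalous Regions in Oral Autofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for flagging anomalous (potentially malignant or otherwise
    lesional) regions of the oral cavity in autofluorescence images. Images are
    cleaned of the imaging device's circular aperture (Deriche-Canny edge
    detection followed by a circular Hough transform), tiled into 64x64
    super-pixels by fixed-depth quadtree division, and described by ten Haralick
    features computed from a full 256-level gray-level co-occurrence matrix at
    0 degrees. Features are ranked by univariate Fisher linear-discriminant
    separation and classified with a k-nearest-neighbour classifier under a
    grouped cross-validation protocol. A seeded synthetic-scene generator
    provides ground-truthed test data so the whole pipeline is reproducible
    without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    class,
    withr
Config/testthat/edition: 3
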