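Package: leafrect
Title: Leaf Geometric Parameters from Calibration-Plate Images with a
    Dynamic Bounding-Rectangle Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures plant-leaf length, width, perimeter and area from
    photographs of a leaf lying inside a rectangular calibration plate that
    carries a black frame with millimetre tick marks.  The pipeline converts
    the photograph to a binary mask, detects the four corners of the plate
    frame, removes projective distortion with an eight-parameter homography,
    reads the physical scale from the tick marks, and converts pixel counts
    to physical units using the leaf's axis-aligned (positive circumscribed)
    rectangle as a dynamic reference object.  A synthetic scene renderer
    generates ground-truthed plate images under configurable camera distance,
    tilt, blur and sensor noise so that every stage of the pipeline can be
    validated without physical hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
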