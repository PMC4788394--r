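Package: cranioball
Title: Cranial Surface Reconstruction from CT Slice Contours with
    Rational Ball Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs smooth 3D surfaces, such as the missing part of a
    fractured parietal bone, from stacks of parallel CT slice images.  Slice
    boundaries are extracted by mathematical morphology, split at detected
    corner points, and fitted with piecewise rational cubic Ball curves
    joined with GC1 geometric continuity; the free shape parameters of each
    segment are optimized by a real-coded genetic algorithm against a
    normalized mean squares error cost.  Fitted 2D contours are stacked at
    equidistant heights and lofted into a surface with a cubic Ball
    contour-blending interpolant, then exported as an STL or OBJ triangle
    mesh.  Includes a synthetic phantom generator (annular skull-like slices
    with configurable fracture gaps) with analytic ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
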