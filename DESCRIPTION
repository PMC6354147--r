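Package: secmorph
Title: Section-Plane Sensitivity of Two-Dimensional Bone-Graft Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico replica of a section-plane sensitivity study for
    two-dimensional morphometry of grafted bone. Generates synthetic
    three-phase (bone / graft / noncalcified) microstructure volumes,
    extracts oblique 2D sections at an original plane and at parallel
    offsets and rotations, segments sections into the three phases by
    luminance thresholds, measures percent areas inside a centered region
    of interest, and quantifies between-plane agreement with Lin's
    concordance correlation coefficient, mean difference with its standard
    deviation, Bland-Altman limits of agreement, and an intraclass
    correlation comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    yaml
Config/testthat/edition: 3
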