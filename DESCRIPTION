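Package: skatemorph
Title: Geometric Morphometrics of Sexual Shape Dimorphism in Skate Pectoral Fins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying sexual shape dimorphism in
    skate (Rajoidei) pectoral fin outlines from 2-D landmark data.
    Implements generalized Procrustes analysis with sliding semilandmarks,
    tangent-space principal component analysis, female-to-male shape-change
    vectors (lengths and angular displacements against a PC-extreme
    baseline), permutation-based comparison of two-point ontogenetic shape
    trajectories, phylogenetic generalized least squares of dimorphism
    magnitude on size-standardized clasper length, sex-specific allometric
    ANCOVAs of endoskeletal traits, and segmented-regression detection of
    the clasper-growth maturity breakpoint. Includes a synthetic-data
    generator that emulates the statistical structure of museum-specimen
    landmark datasets so every stage is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
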