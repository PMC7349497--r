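Package: mealvol
Title: Volumetric Dietary Intake Estimation from Partial 3D Food Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns partial triangular surface meshes of plated food, as produced
    by handheld depth-sensor scanners, into consumed-nutrient estimates. Detects
    hole boundary loops in Wavefront OBJ meshes, closes them with an
    advancing-front patch driven by three front-angle rules and an epsilon vertex
    merge, smooths patch interiors by solving the cotangent-Laplacian harmonic
    system, computes watertight enclosed volumes by the divergence theorem, and
    converts leftover volume to weight and nutrients against a kitchen-reported
    baseline using a pluggable food density table. Includes a deterministic
    synthetic-scan generator (cubes, cones, food-like blobs with punched holes
    and surface noise), plate segmentation by RANSAC plane fitting, seeded item
    splitting, a voxel ray-parity volume oracle, and dietary-study error
    statistics.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
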