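Package: patmap
Title: Patellar Pose Estimation by Surface Mapping of Skin Markers onto a Bone Mesh
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the six degree-of-freedom pose (three positions, three
    Cardan angles) of the patella from skin-surface marker coordinates and a
    CT-derived bone surface mesh. The bone mesh is isotropically remeshed to a
    target edge length, per-face soft-tissue thickness is measured by casting
    rays along outward face normals to the skin surface, and an analysis area
    is selected by thickness thresholding. The pose is found by minimizing the
    surface mapping error, the sum over analysis faces of the absolute
    difference between each face's marker vertical distance and its soft-tissue
    thickness, with a fixed-step derivative-free coordinate-descent optimizer.
    Includes rigid-body math (Cardan angles, least-squares frame fitting),
    STL/PLY/OBJ mesh and CSV/TRC marker input and output, grid and
    Poisson-disk marker generation, a full-factorial parameter-selection study
    with rank-based scoring, and a synthetic knee phantom generator with known
    true poses for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
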