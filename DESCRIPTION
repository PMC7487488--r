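Package: wbafem
Title: Quantified Femoral-Head Weight-Bearing Area and Proximal-Femur
    Finite-Element Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the weight-bearing area of the femoral head in the
    standing position from anteroposterior pelvis radiograph landmarks.
    Landmark constructions on the magnification-corrected radiograph (lateral
    and medial margin lines, center-edge angle) are registered to a 3D
    proximal-femur surface mesh by closed-form planar similarity Procrustes,
    lifted onto a coronal datum plane, and used to trim the femoral-head
    surface together with a 30-degree inferior limit, yielding a crescent
    weight-bearing patch and its area. A small-strain linear-elastic
    tetrahedral finite-element solver with bi-material (cortical/cancellous)
    support compares hip joint-reaction-force loading over the quantified
    patch against the conventional 2 cm circular region and apical point
    load, with Von Mises and principal-stress postprocessing along a
    head-to-neck path. A parametric synthetic-anatomy generator (spherical
    head, cylindrical neck and shaft, matched synthetic radiograph with known
    ground truth) makes the full pipeline testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
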