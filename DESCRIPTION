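Package: ancurve
Title: Anatomical Curve Identification on 3D Surface Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies ridge and valley boundary curves on anatomical
    surfaces represented as unstructured 3D point clouds. Planar transects
    of the surface are summarised by principal curves fitted with penalized
    B-spline smoothers; boundary points are located through the curvature of
    these curves, filtered by landmark-based exclusion rules, and assessed by
    a standardized change-point statistic on first derivatives. Boundary
    curves are completed by corner-constrained, shape-penalized P-spline
    fits. Bounded surfaces are regularised into corresponded semi-landmark
    grids for generalized Procrustes superimposition and principal component
    analysis of shape. Synthetic torso and lip phantom generators with known
    ground truth support validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    splines,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
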