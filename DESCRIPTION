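Package: canvox
Title: Voxel-Grid Analysis of Forest Canopy Space from Terrestrial Laser
    Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: High-resolution voxel-grid analysis of spatiotemporal canopy
    space occupancy in dense planted stands from terrestrial laser scanning
    (TLS) point clouds. Provides point-cloud cleaning (statistical outlier
    removal, minimum-distance subsampling), digital terrain models by
    lowest-point rasterization with bivariate gap interpolation,
    multitemporal coregistration from stem-slice circle fits and a
    least-squares 2D conformal transform with height leveling, per-tree
    crown models that merge a voxelized 3D alpha-shape with direct point
    voxelization, plot-level multi-occupancy voxel grids, crown volume and
    crown intersection volume, canopy-layer aggregation, between-year
    change detection with heat-map export, and a seeded synthetic scene
    generator with a ray-casting scan simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    interp,
    Matrix,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
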