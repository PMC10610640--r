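Package: vinecwsi
Title: Crop Water Stress Index Mapping for Vineyards from Thermal Rasters
    and Point Clouds
Version: 0.1.0
Authors@R:
    person("Vine", "Thermal", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for UAV-based thermal monitoring of vineyard water
    status. Builds canopy height models from digital surface and terrain
    models, masks canopy pixels, classifies ground points in 3D point
    clouds by progressive TIN densification, filters sensor noise,
    computes the simplified Crop Water Stress Index (CWSI) from
    histogram-tail wet and dry reference temperatures on both raster and
    point-cloud data, extracts per-plant statistics on an equal-cell grid
    aligned to the vine rows, estimates per-plant canopy volume by 3D
    convex hulls, and compares data models and flights by linear
    regression. Includes a synthetic vineyard scene generator with known
    ground truth, minimal GeoTIFF/LAS/PLY/XYZ readers and writers, and a
    stage-based command line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
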