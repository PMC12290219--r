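Package: timeraster
Title: Travel-Time Rasters from Friction Surfaces and Point Locations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds raster maps of minimum travel time, in minutes, from
    every cell of an area of interest to the nearest of a set of
    user-supplied point locations. Movement is modelled as least-cost
    traversal of a resistance 'friction surface' (minutes per metre) on
    the 8-connected raster graph, solved by multi-source Dijkstra with
    geodesic (great-circle) or planar edge lengths. Includes friction
    surface preparation (snapping extents to the global 30 arc-second
    lattice, cropping, polygon masking), a pluggable fetch adapter for
    named global surfaces, synthetic surface generation for testing,
    single-band GeoTIFF input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    mgcv,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
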