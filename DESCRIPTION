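Package: tdbscan
Title: Spatiotemporal Density Clustering for Stopover-Site Identification
    in Animal Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies migratory stopover sites in satellite tracking
    data with T-DBSCAN, a density-based spatiotemporal clustering
    algorithm that replaces DBSCAN's minimum-neighbor count with a
    minimum dwell-time test on time-contiguous runs of the spatial
    neighborhood, so revisits of the same site in different periods form
    separate clusters.  Includes a quadtree spatial index and
    convex-hull-guided cluster expansion for large tracks, a classic
    DBSCAN baseline, clustering-comparison metrics (Calinski-Harabasz
    index, recognition difference rate), stopover-site summaries
    (arrival, departure, duration, centroid), a seeded synthetic
    migration-track simulator with ground truth, and CSV/GeoJSON input
    and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
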