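Package: geoepi
Title: Geospatial Clustering and Hospital Proximity Analysis for
    Sentinel Surveillance Case Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Point-pattern and hotspot analysis for hospital-reported case
    data collected through sentinel surveillance networks. Implements the
    average nearest-neighbor index against complete spatial randomness,
    global Moran's I with analytical (randomization and normality) and
    permutation inference, Getis-Ord Gi* local hotspot detection on
    collision-snapped weighted case locations with inverse-distance
    spatial weights, inverse-distance-weighted (IDW) interpolation of
    hotspot z-scores onto a raster surface, and patient-to-hospital
    proximity analysis (great-circle distance matrices, distance bands,
    district contiguity tables). Includes a synthetic case-data generator
    with distance-decay accrual around sentinel hospitals and known ground
    truth for recovery testing, plus readers and writers for delimited
    case tables, GeoJSON (RFC 7946) and ESRI ASCII grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    Matrix,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
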