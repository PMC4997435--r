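Package: stfield
Title: Spatiotemporal Interpolation of Pollutant Fields and Population Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic spatiotemporal interpolation of daily pollutant
    concentrations (such as fine particulate matter, PM2.5) by treating time as
    a scaled third spatial dimension: linear shape-function (barycentric)
    interpolation over a Delaunay tetrahedralization of the (x, y, c*t) point
    cloud, and inverse-distance weighting with a 3D space-time distance.
    Includes k-fold cross-validation with MAE/MSE/RMSE/MARE/R2 error
    statistics, grid search over time scales and IDW configurations,
    population-exposure summaries at census-unit centroids with air-quality
    standard exceedance flags, and a synthetic monitoring-network generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
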