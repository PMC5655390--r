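Package: pmsurface
Title: Spatial Interpolation and Cross-Validation of Urban Particulate Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping urban particulate-matter exposure from sparse
    monitoring networks. Implements inverse-distance weighting, the classical
    radial basis function spline family (thin-plate, multiquadric, inverse
    multiquadric, completely regularized spline, spline with tension), and
    ordinary/universal kriging with empirical semivariogram estimation and
    weighted least-squares variogram fitting (stable, hole-effect, J-Bessel
    and Gaussian models). Interpolators are compared by leave-one-out
    cross-validation scored with MAPE, RMSE, MBE and MAE on Box-Cox
    normalized concentrations. Ships a 48-station PM2.5/PM10 urban
    monitoring table, exceedance summaries against Iranian DOE and US EPA
    air-quality standards, gridded prediction surfaces with ESRI ASCII
    raster export, and a Gaussian-random-field simulator for validating
    every stage against known spatial structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
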