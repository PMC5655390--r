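# Shared fixtures: tiny station networks built in code.

# Wrap bare (locations, values) into a full station_set, mirroring what the
# synthetic generator produces.
toy_station_set <- function(locations, values, values10 = values) {
  locations <- as.matrix(locations)
  n <- nrow(locations)
  station_set(data.frame(
    station_id = seq_len(n),
    name = sprintf("toy-%d", seq_len(n)),
    easting = locations[, 1], northing = locations[, 2],
    n_samples = 1L, fabric = "Toy",
    pm25_mean = values, pm25_se = 0, pm25_min = values, pm25_max = values,
    pm10_mean = values10, pm10_se = 0, pm10_min = values10,
    pm10_max = values10,
    ratio = round(values / values10, 2),
    stringsAsFactors = FALSE
  ), crs_label = "toy planar metres")
}

# Independent exponential-integral oracle by adaptive quadrature.
e1_quadrature <- function(x) {
  stats::integrate(function(t) exp(-t) / t, lower = x, upper = Inf,
                   rel.tol = 1e-10)$value
}

# A scattered, non-degenerate 2-D layout used across interpolator tests.
scatter_layout <- function(n, seed = 42, extent = 100) {
  set.seed(seed)
  cbind(runif(n, 0, extent), runif(n, 0, extent))
}

# Smooth deterministic test field (no randomness): a gentle bump plus tilt.
smooth_field <- function(loc, extent = 100) {
  50 + 10 * sin(loc[, 1] / extent * pi) * cos(loc[, 2] / extent * pi) +
    0.05 * loc[, 1]
}
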