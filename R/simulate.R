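## Synthetic monitoring networks: stationary Gaussian random fields with
## known variogram, optional linear drift, and a positivity floor.

#' Simulate a station network from a Gaussian random field
#'
#' Draws `n_stations` locations uniformly over the bounding box (duplicate
#' locations rejected and redrawn) and values from a zero-mean multivariate
#' normal whose covariance matches the truth variogram:
#' `C(h) = c * (1 - s(h))` for `h > 0` and `C(0) = c0 + c`, i.e.
#' `C(h) = sill - gamma(h)`. An optional linear drift `a0 + ax x + ay y`
#' and the positivity floor are added on top. Simulation is by dense
#' Cholesky factorization — exact, and comfortable up to a few thousand
#' stations.
#'
#' For the hole-effect and J-Bessel families, which are not positive
#' definite at every parameter combination in 2-D, the covariance matrix is
#' validity-checked (smallest eigenvalue >= -1e-8 x trace) and invalid
#' configurations are rejected with an error.
#'
#' The same field is stored as both the PM2.5 and PM10 columns of the
#' returned [station_set()] with `n_samples = 1` and `se = 0`; descriptive
#' summaries are only meaningful on real monitoring tables.
#'
#' @param n_stations number of stations (>= 3).
#' @param bbox numeric `c(xmin, xmax, ymin, ymax)`, metres. Default a
#'   7 x 7 km box, the extent of a mid-sized city network.
#' @param model truth [variogram_model()] (`nugget` = c0, `psill` = c);
#'   `NULL` for a purely deterministic (drift + floor) field. Default a
#'   Gaussian model with nugget 0.1, partial sill 1, range 2000 m.
#' @param drift optional `c(a0, ax, ay)`: intercept and per-metre slopes.
#' @param value_floor constant added so all values stay positive (Box-Cox
#'   needs positivity). Default 50 ug/m3, a typical urban PM level.
#' @param seed integer seed; identical seeds give identical networks. The
#'   caller's RNG state is left untouched.
#' @return A [station_set()] with `crs_label = "synthetic planar metres"`.
#' @export
simulate_grf <- function(n_stations = 48, bbox = c(0, 7000, 0, 7000),
                         model = variogram_model("gaussian", 0.1, 1, 2000),
                         drift = NULL, value_floor = 50, seed = NULL) {
  stopifnot(n_stations >= 3, length(bbox) == 4,
            bbox[2] > bbox[1], bbox[4] > bbox[3],
            is.null(model) || inherits(model, "variogram_model"),
            is.null(drift) || length(drift) == 3)
  with_seed(seed, {
    loc <- .draw_locations(n_stations, bbox)
    mu <- rep(value_floor, n_stations)
    if (!is.null(drift)) {
      mu <- mu + drift[1] + drift[2] * loc[, 1] + drift[3] * loc[, 2]
    }
    vals <- mu
    if (!is.null(model) && (model$psill > 0 || model$nugget > 0)) {
      Sigma <- .grf_covariance(loc, model)
      L <- .safe_chol(Sigma)
      vals <- mu + as.numeric(t(L) %*% stats::rnorm(n_stations))
    }
    if (any(vals <= 0)) {
      stop("simulated values not all positive; raise value_floor",
           call. = FALSE)
    }
    .as_synthetic_station_set(loc, vals)
  })
}

.draw_locations <- function(n, bbox, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    loc <- cbind(stats::runif(n, bbox[1], bbox[2]),
                 stats::runif(n, bbox[3], bbox[4]))
    if (!anyDuplicated(paste(loc[, 1], loc[, 2]))) return(loc)
  }
  stop("could not draw distinct locations", call. = FALSE)
}

.grf_covariance <- function(loc, model) {
  sill <- model$nugget + model$psill
  G <- variogram_eval(model, .cross_dist(loc, loc))
  Sigma <- sill - G
  diag(Sigma) <- sill
  if (model$kind %in% c("hole_effect", "j_bessel")) {
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * sum(diag(Sigma))) {
      stop("variogram parameters give an invalid (non positive-definite) ",
           "covariance in 2-D", call. = FALSE)
    }
  }
  Sigma
}

.safe_chol <- function(Sigma) {
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L)) {
    jit <- 1e-10 * sum(diag(Sigma))
    L <- tryCatch(chol(Sigma + diag(jit, nrow(Sigma))),
                  error = function(e) {
                    stop("covariance not positive definite even after jitter",
                         call. = FALSE)
                  })
  }
  L
}

.as_synthetic_station_set <- function(loc, vals) {
  n <- nrow(loc)
  d <- data.frame(
    station_id = seq_len(n),
    name = sprintf("synthetic-%d", seq_len(n)),
    easting = loc[, 1], northing = loc[, 2],
    n_samples = 1L, fabric = "Synthetic",
    pm25_mean = vals, pm25_se = 0, pm25_min = vals, pm25_max = vals,
    pm10_mean = vals, pm10_se = 0, pm10_min = vals, pm10_max = vals,
    ratio = 1,
    stringsAsFactors = FALSE
  )
  station_set(d, crs_label = "synthetic planar metres")
}

#' Deterministic drift surface of a simulation config
#'
#' Evaluates `value_floor + a0 + ax x + ay y` at targets — the exact truth
#' for drift-only (noiseless) configurations, enabling bias checks such as
#' verifying that universal kriging recovers a plane exactly.
#'
#' @param targets m x 2 matrix of locations.
#' @param drift `c(a0, ax, ay)`.
#' @param value_floor constant offset (default 0).
#' @param model if supplied, must describe a zero-variance field; passing a
#'   stochastic truth model is an error, since the realized surface is then
#'   not deterministic.
#' @return Numeric vector of m truth values.
#' @export
truth_surface <- function(targets, drift, value_floor = 0, model = NULL) {
  if (!is.null(model) &&
      inherits(model, "variogram_model") &&
      (model$psill > 0 || model$nugget > 0)) {
    stop("truth_surface is defined only for drift-only (noiseless) configs",
         call. = FALSE)
  }
  targets <- .as_loc_matrix(targets)
  stopifnot(length(drift) == 3)
  value_floor + drift[1] + drift[2] * targets[, 1] + drift[3] * targets[, 2]
}
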