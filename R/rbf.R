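## Radial basis function exact interpolation: the classical spline family.

.rbf_kinds <- c("thin_plate", "multiquadric", "inverse_multiquadric",
                "completely_regularized_spline", "tension_spline")

.euler_gamma <- 0.577215  # Euler-Mascheroni constant, to published precision

#' Radial basis kernel specification
#'
#' @param kind one of `"thin_plate"`, `"multiquadric"`,
#'   `"inverse_multiquadric"`, `"completely_regularized_spline"`,
#'   `"tension_spline"`.
#' @param sigma positive shape/tension parameter. For every family except
#'   the inverse multiquadric, larger sigma gives a more gradually varying
#'   surface near the data. Interpreted in the (standardized) distance units
#'   the kernel is evaluated in.
#' @return An object of class `rbf_kernel`.
#' @export
rbf_kernel <- function(kind = .rbf_kinds, sigma = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  structure(list(kind = kind, sigma = sigma), class = "rbf_kernel")
}

#' Evaluate a radial basis kernel
#'
#' The five basis functions, with `s = sigma`:
#' \describe{
#'   \item{thin plate}{`(s r)^2 log(s r)`, 0 at the origin}
#'   \item{multiquadric}{`sqrt(r^2 + s^2)`}
#'   \item{inverse multiquadric}{`1 / sqrt(r^2 + s^2)`}
#'   \item{completely regularized spline}{`log(u) + E1(u) + C_E` with
#'     `u = (s r / 2)^2`, `E1` the exponential integral and `C_E` Euler's
#'     constant; the analytic small-`r` limit is 0}
#'   \item{spline with tension}{`log(s r / 2) + K0(s r) + C_E` with `K0` the
#'     modified Bessel function; again 0 in the small-`r` limit}
#' }
#' Additive or multiplicative constants in these forms do not change the
#' fitted surface: the bias term and solved weights absorb them.
#'
#' @param kernel an [rbf_kernel()].
#' @param r nonnegative distances.
#' @return Basis values `phi(r)`.
#' @export
rbf_kernel_eval <- function(kernel, r) {
  stopifnot(inherits(kernel, "rbf_kernel"))
  if (any(r < 0)) stop("distances must be nonnegative", call. = FALSE)
  s <- kernel$sigma
  dm <- dim(r)
  r <- as.numeric(r)
  out <- switch(kernel$kind,
    thin_plate = {
      v <- numeric(length(r))
      pos <- r > 0
      v[pos] <- (s * r[pos])^2 * log(s * r[pos])
      v
    },
    multiquadric = sqrt(r^2 + s^2),
    inverse_multiquadric = 1 / sqrt(r^2 + s^2),
    completely_regularized_spline = {
      u <- (s * r / 2)^2
      v <- numeric(length(u))
      tiny <- u < 1e-8            # series: log(u) + E1(u) + C_E = u - u^2/4 + ...
      v[tiny] <- u[tiny]
      mid <- !tiny & u <= 700
      v[mid] <- log(u[mid]) + pracma::expint_E1(u[mid]) + .euler_gamma
      big <- u > 700              # E1 underflows; log term dominates
      v[big] <- log(u[big]) + .euler_gamma
      v
    },
    tension_spline = {
      x <- s * r
      v <- numeric(length(x))
      tiny <- x < 1e-4            # series: log(x/2) + K0(x) + C_E = x^2/4 + ...
      v[tiny] <- x[tiny]^2 / 4
      mid <- !tiny & x <= 700
      v[mid] <- log(x[mid] / 2) + besselK(x[mid], 0) + .euler_gamma
      big <- x > 700              # K0 underflows
      v[big] <- log(x[big] / 2) + .euler_gamma
      v
    }
  )
  dim(out) <- dm
  out
}

## Isotropic coordinate standardization shared by fit and predict: a common
## centroid shift and a single scale (RMS of the per-axis SDs), so that
## direction ratios -- hence the interpolant -- are not distorted. Raw metre
## distances (1e3-1e4) would over/underflow K0 and E1 at usable sigma.
.rbf_standardize <- function(locations, center = NULL, scale = NULL) {
  center <- center %||% colMeans(locations)
  if (is.null(scale)) {
    scale <- sqrt(mean(apply(locations, 2, stats::var)))
    if (!is.finite(scale) || scale == 0) scale <- 1
  }
  list(x = sweep(locations, 2, center) / scale, center = center, scale = scale)
}

#' Fit an exact radial basis function interpolant
#'
#' Solves the augmented symmetric system
#' `[Phi, 1; 1', 0] [w; b] = [z; 0]` with `Phi_ij = phi(|S_i - S_j|)`, giving
#' an interpolant `Z(s) = sum_i w_i phi(|S_i - s|) + b` that reproduces every
#' training value. Coordinates are standardized internally (isotropically);
#' `sigma` is interpreted in standardized units.
#'
#' @inheritParams idw_predict
#' @param kernel an [rbf_kernel()].
#' @return An object of class `rbf_model` with elements `weights` (n basis
#'   weights), `bias`, `kernel`, and the training centers.
#' @export
rbf_fit <- function(locations, values, kernel = rbf_kernel()) {
  locations <- .as_loc_matrix(locations)
  stopifnot(inherits(kernel, "rbf_kernel"), length(values) == nrow(locations))
  n <- nrow(locations)
  if (n < 2) stop("at least 2 distinct stations required", call. = FALSE)
  if (anyDuplicated(paste(locations[, 1], locations[, 2]))) {
    stop("duplicate centers are not allowed", call. = FALSE)
  }
  std <- .rbf_standardize(locations)
  Phi <- rbf_kernel_eval(kernel, .cross_dist(std$x, std$x))
  A <- rbind(cbind(Phi, 1), c(rep(1, n), 0))
  rhs <- c(values, 0)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop("singular RBF system (", conditionMessage(e),
         "); consider a different sigma", call. = FALSE)
  })
  resid <- A %*% sol - rhs
  scale_z <- max(abs(values), 1)
  if (max(abs(resid)) > 1e-6 * scale_z) {
    warning("RBF system solved with large residual (",
            format(max(abs(resid))), "); sigma may be ill-conditioned")
  }
  structure(
    list(kernel = kernel, centers = locations, std = std,
         weights = sol[seq_len(n)], bias = sol[n + 1], values = values),
    class = "rbf_model"
  )
}

#' Predict from a fitted RBF interpolant
#'
#' Evaluates `Z(s0) = sum_i w_i phi(|S_i - s0|) + b` at each target. Unlike
#' IDW, spline predictions may legitimately rise above the maximum or fall
#' below the minimum of the data.
#'
#' @param model an [rbf_model][rbf_fit()].
#' @param targets m x 2 matrix of prediction locations (same CRS as the
#'   training centers).
#' @return Numeric vector of m predictions.
#' @export
rbf_predict <- function(model, targets) {
  stopifnot(inherits(model, "rbf_model"))
  targets <- .as_loc_matrix(targets)
  t_std <- sweep(targets, 2, model$std$center) / model$std$scale
  Phi0 <- rbf_kernel_eval(model$kernel, .cross_dist(t_std, model$std$x))
  as.numeric(Phi0 %*% model$weights + model$bias)
}

#' @export
predict.rbf_model <- function(object, targets, ...) rbf_predict(object, targets)

#' Select the RBF shape parameter by leave-one-out error
#'
#' Scans a fixed log-spaced grid of sigma values and returns the one with
#' the smallest leave-one-out RMSE on the supplied (already transformed)
#' values; candidates whose linear system fails or produces non-finite
#' predictions are discarded. This mirrors the parameter optimization GIS
#' implementations of these splines apply by default.
#'
#' @inheritParams idw_predict
#' @param kind kernel family, see [rbf_kernel()].
#' @param grid candidate sigmas, in standardized distance units.
#' @return List with `sigma` (the selected value) and `rmse` (its LOO RMSE).
#' @export
rbf_select_sigma <- function(locations, values, kind = .rbf_kinds,
                             grid = 10^seq(-2, 3, length.out = 21)) {
  kind <- match.arg(kind)
  locations <- .as_loc_matrix(locations)
  n <- nrow(locations)
  stopifnot(n >= 3)
  score <- vapply(grid, function(s) {
    k <- rbf_kernel(kind, s)
    pred <- vapply(seq_len(n), function(i) {
      m <- tryCatch(
        suppressWarnings(rbf_fit(locations[-i, , drop = FALSE], values[-i], k)),
        error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      rbf_predict(m, locations[i, , drop = FALSE])
    }, numeric(1))
    if (any(!is.finite(pred))) return(Inf)
    sqrt(mean((pred - values)^2))
  }, numeric(1))
  if (all(!is.finite(score))) {
    stop("no usable sigma in the candidate grid", call. = FALSE)
  }
  best <- which.min(score)
  list(sigma = grid[best], rmse = score[best])
}
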