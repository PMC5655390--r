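## Semivariogram estimation, parametric variogram models, ordinary and
## universal kriging.

.variogram_kinds <- c("stable", "hole_effect", "j_bessel", "gaussian")

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins pairwise distances into `n_lags` uniform lags up to `max_dist` and
#' computes `gamma(h) = sum (z_i - z_j)^2 / (2 N(h))` over pairs in each
#' bin. Empty bins are dropped; each retained bin reports the mean pair
#' distance as its lag center.
#'
#' @inheritParams idw_predict
#' @param n_lags number of uniform distance bins (default 12).
#' @param max_dist maximum pair separation used; default half the maximum
#'   pairwise distance.
#' @return An object of classes `empirical_variogram`/`data.frame` with
#'   columns `dist` (lag center, m), `gamma`, `np` (pair count).
#' @export
empirical_semivariogram <- function(locations, values, n_lags = 12,
                                    max_dist = NULL) {
  locations <- .as_loc_matrix(locations)
  stopifnot(length(values) == nrow(locations), n_lags >= 1)
  if (nrow(locations) < 2) stop("at least 2 stations required", call. = FALSE)
  D <- as.matrix(stats::dist(locations))
  iu <- which(upper.tri(D), arr.ind = TRUE)
  h <- D[iu]
  g <- 0.5 * (values[iu[, 1]] - values[iu[, 2]])^2
  max_dist <- max_dist %||% (max(h) / 2)
  if (!is.numeric(max_dist) || max_dist <= 0) {
    stop("max_dist must be positive", call. = FALSE)
  }
  keep <- h <= max_dist & h > 0
  if (!any(keep)) stop("no station pairs within max_dist", call. = FALSE)
  h <- h[keep]; g <- g[keep]
  breaks <- seq(0, max_dist, length.out = n_lags + 1)
  bin <- cut(h, breaks, include.lowest = TRUE)
  np <- as.integer(table(bin))
  out <- data.frame(
    dist = as.numeric(tapply(h, bin, mean)),
    gamma = as.numeric(tapply(g, bin, mean)),
    np = np
  )
  out <- out[np > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Parametric semivariogram model
#'
#' Semivariance as a function of separation `h`, `gamma(0) = 0` by
#' convention with the nugget appearing only for `h > 0`:
#' \describe{
#'   \item{gaussian}{`c0 + c (1 - exp(-3 h^2 / a^2))`}
#'   \item{stable}{`c0 + c (1 - exp(-3 (h/a)^shape))`, `shape` in (0, 2];
#'     `shape = 2` recovers the Gaussian model}
#'   \item{hole_effect}{`c0 + c (1 - sin(2 pi h / a) / (2 pi h / a))`}
#'   \item{j_bessel}{`c0 + c (1 - J0(2 pi h / a))` with `J0` the Bessel
#'     function of the first kind}
#' }
#' The factor 3 gives `a` the usual practical-range reading for the
#' monotone models: `gamma(a)` is about 95% of the sill.
#'
#' @param kind one of `"stable"`, `"hole_effect"`, `"j_bessel"`,
#'   `"gaussian"`.
#' @param nugget nonnegative nugget variance `c0`.
#' @param psill partial sill `c` (structured variance); nonnegative, with 0
#'   permitted only to express degenerate simulation configs.
#' @param range distance parameter `a` > 0, metres.
#' @param shape stable-model exponent in (0, 2]; ignored by other kinds.
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(kind = .variogram_kinds, nugget = 0, psill = 1,
                            range = 1, shape = 1.5) {
  kind <- match.arg(kind)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  if (kind == "stable" && !(shape > 0 && shape <= 2)) {
    stop("stable shape must lie in (0, 2]", call. = FALSE)
  }
  structure(list(kind = kind, nugget = nugget, psill = psill,
                 range = range, shape = shape),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model %s: nugget %.4g, partial sill %.4g, range %.4g%s>\n",
              x$kind, x$nugget, x$psill, x$range,
              if (x$kind == "stable") sprintf(", shape %.3g", x$shape) else ""))
  invisible(x)
}

#' Evaluate a semivariogram model
#'
#' @param model a [variogram_model()].
#' @param h nonnegative separations (metres); `gamma(0)` is 0.
#' @return Semivariances, same shape as `h`.
#' @export
variogram_eval <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(h < 0)) stop("separations must be nonnegative", call. = FALSE)
  dm <- dim(h)
  h <- as.numeric(h)
  a <- model$range
  s <- switch(model$kind,
    gaussian = 1 - exp(-3 * h^2 / a^2),
    stable = 1 - exp(-3 * (h / a)^model$shape),
    hole_effect = {
      x <- 2 * pi * h / a
      v <- numeric(length(x))
      pos <- x > 0
      v[pos] <- 1 - sin(x[pos]) / x[pos]
      v
    },
    j_bessel = 1 - besselJ(2 * pi * h / a, 0)
  )
  out <- ifelse(h == 0, 0, model$nugget + model$psill * s)
  dim(out) <- dm
  out
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes `sum N(h) (gamma_hat(h) - gamma(h; c0, c, a[, shape]))^2` over
#' the retained lag bins, with pair counts as weights and box constraints
#' `c0 >= 0`, `c > 0`, `a > 0` (and `shape` in (0, 2] for the stable
#' model). Several range starting points are tried and the best optimum
#' kept.
#'
#' @param emp an [empirical_semivariogram()] with at least 3 retained bins.
#' @param kind model family, see [variogram_model()].
#' @return A fitted [variogram_model()] with attributes `objective` (the
#'   attained WLS criterion) and `emp` (the empirical variogram used).
#' @export
fit_variogram <- function(emp, kind = .variogram_kinds) {
  kind <- match.arg(kind)
  stopifnot(inherits(emp, "empirical_variogram"))
  if (nrow(emp) < 3) {
    stop("need at least 3 variogram bins, got ", nrow(emp), call. = FALSE)
  }
  gmax <- max(emp$gamma)
  if (gmax == 0) {
    ## constant field: zero-variance degenerate model
    return(structure(variogram_model(kind, 0, 0, max(emp$dist)),
                     objective = 0, emp = emp))
  }
  sill0 <- mean(utils::tail(emp$gamma, max(1L, nrow(emp) %/% 3)))
  maxlag <- max(emp$dist)
  lb_a <- min(emp$dist) / 2
  has_shape <- kind == "stable"
  obj <- function(p) {
    m <- variogram_model(kind, p[1], p[2], p[3],
                         if (has_shape) p[4] else 1.5)
    sum(emp$np * (emp$gamma - variogram_eval(m, emp$dist))^2)
  }
  lower <- c(0, 1e-8 * gmax, lb_a)
  upper <- c(2 * gmax, 4 * gmax, 4 * maxlag)
  if (has_shape) { lower <- c(lower, 0.1); upper <- c(upper, 2) }
  best <- NULL
  fails <- character()
  for (afrac in c(0.15, 0.3, 0.6, 1)) {
    start <- c(0.1 * sill0, 0.9 * sill0, afrac * maxlag)
    start <- pmax(pmin(start, upper[1:3]), lower[1:3])
    if (has_shape) start <- c(start, 1.5)
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) { fails <- c(fails, fit); next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("variogram fit failed to converge from any start: ",
         paste(unique(fails), collapse = "; "), call. = FALSE)
  }
  p <- best$par
  out <- variogram_model(kind, p[1], max(p[2], 1e-12 * gmax), p[3],
                         if (has_shape) p[4] else 1.5)
  attr(out, "objective") <- best$value
  attr(out, "emp") <- emp
  out
}

#' Ordinary and universal kriging prediction
#'
#' Ordinary kriging solves, per target `s0`, the augmented system
#' `[Gamma, 1; 1', 0] [lambda; m] = [gamma(., s0); 1]`, i.e. the best linear
#' unbiased predictor under a constant unknown mean, with weights summing
#' to 1. Universal kriging replaces the single constraint by the drift
#' basis `{1, x, y}` (first-order drift), forcing exact reproduction of any
#' planar trend; `drift_order = 0` reduces identically to ordinary kriging.
#' The kriging variance `lambda' gamma0 + nu' f0` is reported per target.
#'
#' With `gamma(0) = 0` the predictor is exact at data sites; when the
#' nugget is interpreted as measurement error one would instead filter it
#' (not done here -- see the package vignette).
#'
#' @inheritParams idw_predict
#' @param model a fitted [variogram_model()].
#' @param mode `"ordinary"` or `"universal"`.
#' @param drift_order 0 or 1 (universal only); first-order uses the basis
#'   `{1, x, y}` on internally standardized coordinates.
#' @param check_hull warn when targets fall outside the convex hull of the
#'   stations (extrapolation). Disabled inside cross-validation loops.
#' @param details also return the kriging weight matrix.
#' @return List with `predictions`, `variance` (both length m) and, when
#'   `details = TRUE`, `weights` (n x m).
#' @export
kriging_predict <- function(locations, values, targets, model,
                            mode = c("ordinary", "universal"),
                            drift_order = 1, check_hull = TRUE,
                            details = FALSE) {
  mode <- match.arg(mode)
  locations <- .as_loc_matrix(locations)
  targets <- .as_loc_matrix(targets)
  stopifnot(inherits(model, "variogram_model"),
            length(values) == nrow(locations),
            drift_order %in% c(0, 1))
  n <- nrow(locations)
  if (n < 3) stop("kriging requires at least 3 stations", call. = FALSE)
  if (check_hull) .warn_outside_hull(locations, targets)

  universal <- mode == "universal" && drift_order >= 1
  ## standardized coordinates for the drift basis keep the system well scaled
  std <- .rbf_standardize(rbind(locations, targets))
  ls <- std$x[seq_len(n), , drop = FALSE]
  ts <- std$x[n + seq_len(nrow(targets)), , drop = FALSE]

  Gam <- variogram_eval(model, .cross_dist(locations, locations))
  Fmat <- if (universal) cbind(1, ls) else matrix(1, n, 1)
  p <- ncol(Fmat)
  A <- rbind(cbind(Gam, Fmat), cbind(t(Fmat), matrix(0, p, p)))
  g0 <- variogram_eval(model, .cross_dist(locations, targets))  # n x m
  f0 <- if (universal) rbind(1, t(ts)) else matrix(1, 1, nrow(targets))
  B <- rbind(g0, f0)

  sol <- .solve_kriging(A, B, n)
  lambda <- sol[seq_len(n), , drop = FALSE]
  nu <- sol[n + seq_len(p), , drop = FALSE]
  pred <- as.numeric(crossprod(lambda, values))
  kvar <- colSums(lambda * g0) + colSums(nu * f0)
  kvar <- pmax(kvar, 0)  # clamp tiny negative round-off
  out <- list(predictions = pred, variance = as.numeric(kvar))
  if (details) out$weights <- lambda
  out
}

## Solve the kriging system, guarding against near-singularity: very smooth
## models (e.g. a Gaussian variogram with range far beyond the data extent)
## make A numerically rank-deficient, and LU can return garbage without
## erroring. Accept a solution only if its residual is small, escalating a
## diagonal jitter on the data block otherwise.
.solve_kriging <- function(A, B, n) {
  scale_A <- max(abs(A))
  scale_B <- max(abs(B), 1e-300)
  for (jit in c(0, 1e-10, 1e-8, 1e-6, 1e-4) * scale_A) {
    Aj <- A
    if (jit > 0) diag(Aj)[seq_len(n)] <- diag(Aj)[seq_len(n)] + jit
    rc <- tryCatch(rcond(Aj), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-10) next
    sol <- tryCatch(solve(Aj, B), error = function(e) NULL)
    if (is.null(sol)) next
    resid <- max(abs(Aj %*% sol - B)) / scale_B
    if (is.finite(resid) && resid < 1e-6) {
      if (jit > 0) {
        warning("near-singular kriging matrix; solved with diagonal jitter ",
                format(jit), call. = FALSE)
      }
      return(sol)
    }
  }
  stop("kriging system is singular even after jitter; check for ",
       "near-duplicate stations or a degenerate drift", call. = FALSE)
}

.warn_outside_hull <- function(locations, targets) {
  if (nrow(locations) < 3) return(invisible())
  hull <- locations[grDevices::chull(locations), , drop = FALSE]
  k <- nrow(hull)
  inside <- rep(TRUE, nrow(targets))
  for (i in seq_len(k)) {
    a <- hull[i, ]; b <- hull[if (i == k) 1 else i + 1, ]
    ## chull returns vertices clockwise; points left of an edge are outside
    cr <- (b[1] - a[1]) * (targets[, 2] - a[2]) -
      (b[2] - a[2]) * (targets[, 1] - a[1])
    inside <- inside & cr <= 1e-9 * max(abs(hull))
  }
  n_out <- sum(!inside)
  if (n_out > 0) {
    warning(n_out, " target(s) outside the station convex hull; ",
            "predictions there are extrapolations", call. = FALSE)
  }
  invisible()
}
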