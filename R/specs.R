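## Interpolator method specifications: lightweight configuration objects that
## loocv(), compare_models() and predict_surface() know how to fit and apply.

#' IDW method specification
#'
#' @param power positive distance exponent.
#' @param k optional k-nearest neighbourhood; default global.
#' @return An `interp_spec` of subclass `idw_spec`.
#' @export
idw_spec <- function(power = 1, k = NULL) {
  stopifnot(power > 0, is.null(k) || k >= 1)
  structure(list(power = power, k = k,
                 label = sprintf("IDW Power %g", power),
                 family = "IDW", fn = sprintf("Power %g", power)),
            class = c("idw_spec", "interp_spec"))
}

#' RBF method specification
#'
#' @param kind kernel family, see [rbf_kernel()]. Default the completely
#'   regularized spline.
#' @param sigma shape parameter in standardized distance units, or `NULL`
#'   (default) to select it by internal leave-one-out RMSE via
#'   [rbf_select_sigma()].
#' @return An `interp_spec` of subclass `rbf_spec`.
#' @export
rbf_spec <- function(kind = "completely_regularized_spline", sigma = NULL) {
  kind <- match.arg(kind, .rbf_kinds)
  stopifnot(is.null(sigma) || sigma > 0)
  fn <- gsub("_", " ", kind)
  substr(fn, 1, 1) <- toupper(substr(fn, 1, 1))
  structure(list(kind = kind, sigma = sigma,
                 label = paste("RBF", fn), family = "RBF", fn = fn),
            class = c("rbf_spec", "interp_spec"))
}

#' Kriging method specification
#'
#' @param mode `"ordinary"` or `"universal"`.
#' @param model variogram family, see [variogram_model()].
#' @param drift_order 0 or 1 (universal only).
#' @param n_lags,max_dist empirical-variogram binning passed to
#'   [empirical_semivariogram()].
#' @param refit_per_fold refit the variogram inside every cross-validation
#'   fold instead of once on the full dataset (default `FALSE`, mirroring
#'   standard GIS cross-validation behaviour).
#' @param variogram optional pre-fitted [variogram_model()]; default `NULL`
#'   fits one from the data.
#' @return An `interp_spec` of subclass `kriging_spec`.
#' @export
kriging_spec <- function(mode = c("ordinary", "universal"),
                         model = .variogram_kinds, drift_order = 1,
                         n_lags = 12, max_dist = NULL,
                         refit_per_fold = FALSE, variogram = NULL) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  stopifnot(drift_order %in% c(0, 1),
            is.null(variogram) || inherits(variogram, "variogram_model"))
  fam <- if (mode == "ordinary") "OK" else "UK"
  fn <- gsub("_", " ", model)
  substr(fn, 1, 1) <- toupper(substr(fn, 1, 1))
  structure(list(mode = mode, model = model, drift_order = drift_order,
                 n_lags = n_lags, max_dist = max_dist,
                 refit_per_fold = refit_per_fold, variogram = variogram,
                 label = paste(fam, fn), family = fam, fn = fn),
            class = c("kriging_spec", "interp_spec"))
}

#' @export
print.interp_spec <- function(x, ...) {
  cat("<interp_spec:", x$label, ">\n")
  invisible(x)
}

## Fit whatever a spec describes on (locations, values) and predict at
## targets. Context-dependent pieces (fitted variogram, selected sigma) may
## already be frozen into the spec by .prepare_spec().
.spec_predict <- function(spec, locations, values, targets) {
  UseMethod(".spec_predict")
}

#' @export
.spec_predict.idw_spec <- function(spec, locations, values, targets) {
  idw_predict(locations, values, targets, power = spec$power, k = spec$k)
}

#' @export
.spec_predict.rbf_spec <- function(spec, locations, values, targets) {
  sigma <- spec$sigma
  if (is.null(sigma)) {
    sigma <- rbf_select_sigma(locations, values, spec$kind)$sigma
  }
  m <- rbf_fit(locations, values, rbf_kernel(spec$kind, sigma))
  rbf_predict(m, targets)
}

## Variogram estimation for a kriging spec. Under a first-order drift the
## raw-value variogram is drift-contaminated (it keeps rising and the fit
## degenerates to ranges far beyond the data extent), so universal-kriging
## specs use the classical residual variogram: semivariances of the
## least-squares planar-trend residuals.
.fit_spec_variogram <- function(spec, locations, values) {
  v <- values
  if (spec$mode == "universal" && spec$drift_order >= 1) {
    std <- .rbf_standardize(locations)
    v <- stats::lm.fit(cbind(1, std$x), values)$residuals
  }
  emp <- empirical_semivariogram(locations, v, spec$n_lags, spec$max_dist)
  fit_variogram(emp, spec$model)
}

#' @export
.spec_predict.kriging_spec <- function(spec, locations, values, targets) {
  vg <- spec$variogram
  if (is.null(vg)) {
    vg <- .fit_spec_variogram(spec, locations, values)
  }
  kriging_predict(locations, values, targets, vg, mode = spec$mode,
                  drift_order = spec$drift_order,
                  check_hull = FALSE)$predictions
}

## Freeze data-dependent choices once on the full dataset so that LOOCV
## folds reuse them (variogram fitted once; sigma selected once), unless the
## spec asks for per-fold refitting.
.prepare_spec <- function(spec, locations, values) {
  if (inherits(spec, "kriging_spec") && is.null(spec$variogram) &&
      !isTRUE(spec$refit_per_fold)) {
    spec$variogram <- .fit_spec_variogram(spec, locations, values)
  }
  if (inherits(spec, "rbf_spec") && is.null(spec$sigma)) {
    spec$sigma <- rbf_select_sigma(locations, values, spec$kind)$sigma
  }
  spec
}
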