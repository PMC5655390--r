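## Leave-one-out cross-validation and the four error statistics.

#' Leave-one-out cross-validation of an interpolator
#'
#' For each station `i`, the method described by `spec` is fitted to the
#' remaining stations on the Box-Cox scale, predicts at station `i`, and
#' the prediction is back-transformed to the concentration scale. Data-
#' dependent method choices (fitted variogram, RBF shape parameter) are
#' made once on the full dataset and reused across folds, mirroring
#' standard GIS cross-validation (kriging specs can opt into per-fold
#' refits). The result is deterministic given the inputs and invariant to
#' station order.
#'
#' @param stations a [station_set()] with at least 3 stations.
#' @param pollutant `"pm25"` or `"pm10"`.
#' @param spec an [idw_spec()], [rbf_spec()] or [kriging_spec()].
#' @param lambda Box-Cox power; default [default_lambda()] for the
#'   pollutant (0.6 for PM2.5, 0.1 for PM10).
#' @return An object of classes `cv_result`/`data.frame` with columns
#'   `station_id`, `observed`, `predicted` (concentration scale, ug/m3),
#'   `observed_t`, `predicted_t` (Box-Cox scale), and attributes
#'   `method_label`, `pollutant`, `lambda`.
#' @export
loocv <- function(stations, pollutant = c("pm25", "pm10"), spec,
                  lambda = NULL) {
  stopifnot(inherits(stations, "station_set"), inherits(spec, "interp_spec"))
  pollutant <- match.arg(pollutant)
  lambda <- lambda %||% default_lambda(pollutant)
  sv <- station_values(stations, pollutant)
  n <- length(sv$values)
  if (n < 3) stop("LOOCV needs at least 3 stations", call. = FALSE)

  z <- boxcox_forward(sv$values, lambda)
  spec <- .prepare_spec(spec, sv$locations, z)
  pred_t <- vapply(seq_len(n), function(i) {
    p <- tryCatch(
      .spec_predict(spec, sv$locations[-i, , drop = FALSE], z[-i],
                    sv$locations[i, , drop = FALSE]),
      error = function(e) {
        stop(sprintf("%s failed on fold %d (station %s): %s", spec$label, i,
                     sv$station_id[i], conditionMessage(e)), call. = FALSE)
      })
    as.numeric(p)
  }, numeric(1))
  pred <- tryCatch(boxcox_inverse(pred_t, lambda), error = function(e) {
    stop(spec$label, ": back-transform failed (", conditionMessage(e), ")",
         call. = FALSE)
  })

  ord <- order(sv$station_id)
  out <- data.frame(
    station_id = sv$station_id[ord],
    observed = sv$values[ord],
    predicted = pred[ord],
    observed_t = z[ord],
    predicted_t = pred_t[ord]
  )
  class(out) <- c("cv_result", "data.frame")
  attr(out, "method_label") <- spec$label
  attr(out, "pollutant") <- pollutant
  attr(out, "lambda") <- lambda
  out
}

#' Cross-validation error statistics
#'
#' The four accuracy statistics over paired predictions `I_i` and
#' observations `O_i`:
#' \describe{
#'   \item{MAPE}{`100/N * sum |(I_i - O_i) / O_i|` (percent)}
#'   \item{RMSE}{`sqrt(sum (I_i - O_i)^2 / N)`}
#'   \item{MBE}{`sum (I_i - O_i) / N` (signed; cancellation possible)}
#'   \item{MAE}{`sum |I_i - O_i| / N`}
#' }
#' Always `|MBE| <= MAE <= RMSE`, with `MAE = RMSE` only when all absolute
#' residuals are equal; MAPE is invariant to a common positive rescaling of
#' both series.
#'
#' @param cv a [loocv()] result, or any data frame with `observed` and
#'   `predicted` columns (plus `observed_t`/`predicted_t` for the
#'   transformed scale).
#' @param scale `"concentration"` (after Box-Cox back-transform; the
#'   headline scale for MAPE comparisons) or `"transformed"`.
#' @return Named numeric vector `mape`, `rmse`, `mbe`, `mae`.
#' @export
cv_metrics <- function(cv, scale = c("concentration", "transformed")) {
  scale <- match.arg(scale)
  if (scale == "concentration") {
    O <- cv$observed; I <- cv$predicted
  } else {
    O <- cv$observed_t; I <- cv$predicted_t
  }
  stopifnot(length(O) == length(I), length(O) > 0)
  if (any(O == 0)) {
    id <- if ("station_id" %in% names(cv)) cv$station_id[O == 0][1] else which(O == 0)[1]
    stop("MAPE undefined: observed value is zero at station ", id,
         call. = FALSE)
  }
  e <- I - O
  c(mape = 100 * mean(abs(e / O)),
    rmse = sqrt(mean(e^2)),
    mbe = mean(e),
    mae = mean(abs(e)))
}

#' The 11-method comparison grid
#'
#' The default model grid compared in the packaged analysis: the completely
#' regularized spline RBF, IDW with powers 1 and 2, and ordinary plus
#' universal kriging under the stable, hole-effect, J-Bessel and Gaussian
#' variogram models.
#'
#' @return Named list of `interp_spec` objects.
#' @export
default_model_grid <- function() {
  grid <- c(
    list(rbf_spec("completely_regularized_spline"),
         idw_spec(1), idw_spec(2)),
    lapply(.variogram_kinds, function(k) kriging_spec("ordinary", k)),
    lapply(.variogram_kinds, function(k) kriging_spec("universal", k))
  )
  stats::setNames(grid, vapply(grid, `[[`, "", "label"))
}

#' Cross-validated comparison of interpolation methods
#'
#' Runs [loocv()] for every spec in the grid and tabulates the four error
#' statistics on both the concentration and the Box-Cox scale. Methods are
#' ranked by concentration-scale MAPE.
#'
#' @inheritParams loocv
#' @param specs list of `interp_spec` objects; default
#'   [default_model_grid()].
#' @return An object of classes `metrics_table`/`data.frame` with columns
#'   `pollutant`, `family`, `fn`, `scale`, `mape`, `rmse`, `mbe`, `mae`,
#'   and attribute `ranking` (method labels, best concentration-scale MAPE
#'   first).
#' @export
compare_models <- function(stations, pollutant = c("pm25", "pm10"),
                           specs = default_model_grid(), lambda = NULL) {
  pollutant <- match.arg(pollutant)
  stopifnot(length(specs) >= 1)
  rows <- lapply(specs, function(sp) {
    cv <- loocv(stations, pollutant, sp, lambda)
    do.call(rbind, lapply(c("concentration", "transformed"), function(sc) {
      m <- cv_metrics(cv, sc)
      data.frame(pollutant = pollutant, family = sp$family, fn = sp$fn,
                 scale = sc, mape = m[["mape"]], rmse = m[["rmse"]],
                 mbe = m[["mbe"]], mae = m[["mae"]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  conc <- out[out$scale == "concentration", ]
  ranking <- paste(conc$family, conc$fn)[order(conc$mape)]
  class(out) <- c("metrics_table", "data.frame")
  attr(out, "ranking") <- ranking
  out
}

#' Write a metrics table to CSV
#'
#' @param x a [compare_models()] result.
#' @param path output file.
#' @export
write_metrics <- function(x, path) {
  stopifnot(inherits(x, "metrics_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
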