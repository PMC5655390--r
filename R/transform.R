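## Box-Cox normalization of skewed concentration data and its inverse.

#' Box-Cox power transform
#'
#' `y = (x^lambda - 1) / lambda` for `lambda != 0`, `y = log(x)` for
#' `lambda = 0`. The transform is strictly increasing for every lambda, so
#' ordering of concentrations is preserved. Station PM means are normalized
#' with fixed powers (0.6 for PM2.5, 0.1 for PM10) before interpolation and
#' predictions are mapped back with [boxcox_inverse()] before any
#' concentration-scale error metric.
#'
#' @param x positive numeric vector (concentrations, ug/m3).
#' @param lambda power; finite scalar, 0 selects the log branch.
#' @return Transformed values, same length as `x`.
#' @export
boxcox_forward <- function(x, lambda) {
  stopifnot(is.numeric(x), is.numeric(lambda), length(lambda) == 1,
            is.finite(lambda))
  bad <- which(!(x > 0))
  if (length(bad) > 0) {
    stop("Box-Cox requires strictly positive values; offending index(es): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' Inverse Box-Cox transform
#'
#' Exact inverse of [boxcox_forward()]: `x = (1 + lambda*y)^(1/lambda)` for
#' `lambda != 0`, `x = exp(y)` for `lambda = 0`.
#'
#' @param y transformed values; for `lambda != 0` every element must satisfy
#'   `1 + lambda*y > 0` (the image of the positive half-line).
#' @inheritParams boxcox_forward
#' @return Positive concentrations.
#' @export
boxcox_inverse <- function(y, lambda) {
  stopifnot(is.numeric(y), is.numeric(lambda), length(lambda) == 1,
            is.finite(lambda))
  if (lambda == 0) return(exp(y))
  base <- 1 + lambda * y
  bad <- which(!(base > 0))
  if (length(bad) > 0) {
    stop("values outside the Box-Cox image (1 + lambda*y <= 0) at index(es): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  base^(1 / lambda)
}

#' Maximum-likelihood Box-Cox power
#'
#' Profile-likelihood estimate of lambda under the normal model, maximizing
#' `-n/2 log(sigma2(lambda)) + (lambda - 1) * sum(log x)`. Provided for
#' exploration; the packaged analyses use the fixed powers 0.6 (PM2.5) and
#' 0.1 (PM10) rather than re-estimating.
#'
#' @param x positive numeric vector.
#' @param interval search interval for lambda.
#' @return Scalar lambda.
#' @export
boxcox_lambda <- function(x, interval = c(-2, 2)) {
  stopifnot(all(x > 0), length(x) >= 3)
  n <- length(x)
  slx <- sum(log(x))
  negll <- function(l) {
    y <- boxcox_forward(x, l)
    n / 2 * log(stats::var(y) * (n - 1) / n) - (l - 1) * slx
  }
  stats::optimize(negll, interval)$minimum
}

#' Default normalization power per pollutant
#'
#' The fixed Box-Cox coefficients used throughout the packaged analyses:
#' 0.6 for PM2.5 and 0.1 for PM10.
#'
#' @param pollutant `"pm25"` or `"pm10"`.
#' @return Scalar lambda.
#' @export
default_lambda <- function(pollutant = c("pm25", "pm10")) {
  switch(match.arg(pollutant), pm25 = 0.6, pm10 = 0.1)
}
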