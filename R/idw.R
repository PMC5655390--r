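## Inverse-distance-weighted interpolation.

.as_loc_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != 2) stop("locations must be n x 2", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

.cross_dist <- function(a, b) {
  ## Euclidean distances between rows of a (n x 2) and rows of b (m x 2)
  da <- rowSums(a^2)
  db <- rowSums(b^2)
  d2 <- outer(da, db, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Inverse-distance-weighted prediction
#'
#' Predicts at each target as the weighted mean of station values with
#' weights `w_i = 1 / d_i^p`: `Z_j = sum(w_i z_i) / sum(w_i)`. A target that
#' coincides with a station (zero distance) returns that station's value
#' exactly. As a convex combination of the data, IDW predictions never leave
#' the observed value range; as `p` grows the predictor approaches
#' nearest-neighbour interpolation.
#'
#' @param locations n x 2 matrix of station coordinates (metres).
#' @param values numeric station values, length n.
#' @param targets m x 2 matrix of prediction locations.
#' @param power positive distance exponent `p`; the packaged comparisons use
#'   1 and 2.
#' @param k optional neighbourhood size: predict from the `k` nearest
#'   stations only. Default `NULL` uses all stations (global neighbourhood).
#' @return Numeric vector of m predictions.
#' @export
idw_predict <- function(locations, values, targets, power = 1, k = NULL) {
  locations <- .as_loc_matrix(locations)
  targets <- .as_loc_matrix(targets)
  stopifnot(length(values) == nrow(locations))
  if (!is.numeric(power) || length(power) != 1 || power <= 0) {
    stop("power must be a positive scalar", call. = FALSE)
  }
  if (!is.null(k)) {
    stopifnot(k >= 1)
    k <- min(k, nrow(locations))
  }
  if (nrow(locations) < 1) stop("at least one station required", call. = FALSE)

  D <- .cross_dist(targets, locations)
  vapply(seq_len(nrow(targets)), function(j) {
    d <- D[j, ]
    idx <- seq_along(d)
    if (!is.null(k)) idx <- order(d)[seq_len(k)]
    d <- d[idx]
    hit <- which(d == 0)
    if (length(hit) > 0) return(values[idx][hit[1]])
    w <- 1 / d^power
    sum(w * values[idx]) / sum(w)
  }, numeric(1))
}
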