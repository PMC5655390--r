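## Regular prediction grids and ESRI ASCII raster interchange.

#' Create an empty prediction grid
#'
#' Lays a regular raster of square cells over a bounding box. Cell counts
#' are `ceiling(extent / cell_size)`, so the grid always covers the box;
#' predictions are made at cell centers, and the origin is the lower-left
#' *corner* (ESRI convention).
#'
#' @param bbox numeric `c(xmin, xmax, ymin, ymax)`, metres.
#' @param cell_size cell edge length, metres (> 0).
#' @param nodata sentinel written for missing cells (default -9999).
#' @return An object of class `prediction_grid` with elements `origin`,
#'   `cell_size`, `n_cols`, `n_rows`, `values` (a `n_rows x n_cols` matrix,
#'   row 1 = northernmost row, or `NULL` while unfilled) and `nodata`.
#' @export
make_grid <- function(bbox, cell_size, nodata = -9999) {
  stopifnot(length(bbox) == 4, is.numeric(bbox))
  if (!(cell_size > 0)) stop("cell_size must be positive", call. = FALSE)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop("degenerate or inverted bbox", call. = FALSE)
  }
  structure(list(
    origin = c(bbox[1], bbox[3]),
    cell_size = cell_size,
    n_cols = as.integer(ceiling((bbox[2] - bbox[1]) / cell_size)),
    n_rows = as.integer(ceiling((bbox[4] - bbox[3]) / cell_size)),
    values = NULL,
    nodata = nodata
  ), class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat(sprintf("<prediction_grid: %d x %d cells of %g m, origin (%g, %g)%s>\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2],
              if (is.null(x$values)) ", unfilled" else ""))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a [make_grid()] object.
#' @return Matrix with `n_rows * n_cols` rows and columns
#'   `easting`/`northing`, ordered row-major from the northernmost row,
#'   west to east (the order raster rows are serialized in).
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "prediction_grid"))
  xs <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ys <- grid$origin[2] + (rev(seq_len(grid$n_rows)) - 0.5) * grid$cell_size
  cbind(easting = rep(xs, times = grid$n_rows),
        northing = rep(ys, each = grid$n_cols))
}

#' Interpolate a concentration surface over a grid
#'
#' Predicts at every cell center on the Box-Cox scale with the given
#' method and back-transforms to ug/m3. Deterministic given its inputs.
#'
#' @inheritParams loocv
#' @param grid an empty or previously filled [make_grid()] object.
#' @return The grid with `values` filled (`n_rows x n_cols`, row 1 north).
#' @export
predict_surface <- function(stations, pollutant = c("pm25", "pm10"), spec,
                            grid, lambda = NULL) {
  stopifnot(inherits(stations, "station_set"), inherits(spec, "interp_spec"),
            inherits(grid, "prediction_grid"))
  pollutant <- match.arg(pollutant)
  lambda <- lambda %||% default_lambda(pollutant)
  sv <- station_values(stations, pollutant)
  z <- boxcox_forward(sv$values, lambda)
  spec <- .prepare_spec(spec, sv$locations, z)
  pred_t <- .spec_predict(spec, sv$locations, z, grid_centers(grid))
  pred <- boxcox_inverse(pred_t, lambda)
  grid$values <- matrix(pred, nrow = grid$n_rows, ncol = grid$n_cols,
                        byrow = TRUE)
  grid
}

#' Write a grid as an ESRI ASCII raster
#'
#' Standard `.asc` layout: six header lines (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by one line per row,
#' north to south.
#'
#' @param grid a filled [prediction_grid][make_grid()].
#' @param path output file.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "prediction_grid"))
  if (is.null(grid$values)) stop("grid is unfilled", call. = FALSE)
  v <- grid$values
  v[!is.finite(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$origin[1], scientific = FALSE)),
    paste("yllcorner", format(grid$origin[2], scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", grid$nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' Round-trip companion to [write_ascii_grid()]; nodata cells become `NA`.
#'
#' @param path an `.asc` file.
#' @return A filled [prediction_grid][make_grid()].
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(
    as.numeric(vapply(kv, `[`, "", 2)),
    tolower(vapply(kv, `[`, "", 1)))
  required <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")
  if (!all(required %in% names(vals))) {
    stop("malformed ASCII grid header", call. = FALSE)
  }
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(vals["nrows"], vals["ncols"]))) {
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  }
  m[m == vals["nodata_value"]] <- NA
  g <- make_grid(unname(c(vals["xllcorner"],
                          vals["xllcorner"] + vals["ncols"] * vals["cellsize"],
                          vals["yllcorner"],
                          vals["yllcorner"] + vals["nrows"] * vals["cellsize"])),
                 vals[["cellsize"]], nodata = vals[["nodata_value"]])
  g$n_cols <- as.integer(vals["ncols"])
  g$n_rows <- as.integer(vals["nrows"])
  g$values <- m
  g
}
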