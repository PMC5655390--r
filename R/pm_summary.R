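## Descriptive exposure summaries against air-quality standards.

#' Built-in air-quality standards registry
#'
#' Regulatory PM thresholds shipped with the package (Iranian DOE annual
#' and 24-h limits, US EPA 24-h limits), read from the packaged YAML
#' registry.
#'
#' @return Data frame with columns `label`, `pollutant`, `threshold`
#'   (ug/m3), `averaging`, `agency`. Exceedance is always "above the
#'   threshold is a violation".
#' @export
air_quality_standards <- function() {
  path <- system.file("extdata", "standards.yaml", package = "pmsurface",
                      mustWork = TRUE)
  reg <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(names(reg), function(nm) {
    s <- reg[[nm]]
    data.frame(label = nm, pollutant = s$pollutant,
               threshold = as.numeric(s$threshold),
               averaging = s$averaging, agency = s$agency,
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(out$threshold > 0))
  out
}

#' Sample-count-weighted mean concentration
#'
#' `sum(mean_i * n_i) / sum(n_i)` over stations: the network-wide mean with
#' each station's mean weighted by how many samples were collected there.
#' Always lies between the smallest and largest station mean.
#'
#' @inheritParams loocv
#' @return Scalar concentration, ug/m3.
#' @export
pm_weighted_mean <- function(stations, pollutant = c("pm25", "pm10")) {
  stopifnot(inherits(stations, "station_set"))
  pollutant <- match.arg(pollutant)
  d <- stations$stations
  if (nrow(d) == 0) stop("empty station set", call. = FALSE)
  n <- d$n_samples
  if (any(is.na(n))) stop("missing sample counts", call. = FALSE)
  m <- d[[paste0(pollutant, "_mean")]]
  sum(m * n) / sum(n)
}

#' Fraction of stations beyond a regulatory threshold
#'
#' Share of station means strictly greater than (or, for
#' `comparator = "less"`, strictly less than) a threshold, as a percentage
#' rounded to 2 decimals. Computed over station means, not raw samples.
#' For any threshold the "greater" fraction and its complement (computed
#' with `<=` internally) sum to 100.
#'
#' @inheritParams loocv
#' @param threshold concentration threshold, ug/m3 (> 0).
#' @param comparator `"greater"` (exceedance) or `"less"` (compliance);
#'   both strict, so the two need not sum to 100 when a station mean equals
#'   the threshold exactly.
#' @return Percentage in \[0, 100\], rounded to 2 decimals.
#' @export
exceedance_fraction <- function(stations, pollutant = c("pm25", "pm10"),
                                threshold, comparator = c("greater", "less")) {
  stopifnot(inherits(stations, "station_set"), threshold > 0)
  pollutant <- match.arg(pollutant)
  comparator <- match.arg(comparator)
  m <- stations$stations[[paste0(pollutant, "_mean")]]
  if (length(m) == 0) stop("empty station set", call. = FALSE)
  frac <- if (comparator == "greater") mean(m > threshold) else mean(m < threshold)
  round(100 * frac, 2)
}

#' PM2.5/PM10 ratio summary
#'
#' Ratios recomputed from the station means (not read from the printed
#' ratio column), with min/max reported to 2 decimals alongside the
#' stations attaining them.
#'
#' @inheritParams loocv
#' @return List with `min`, `max` (rounded to 2 decimals), `mean`
#'   (unrounded), `argmin`, `argmax` (station ids) and the full `ratios`
#'   vector.
#' @export
ratio_summary <- function(stations) {
  stopifnot(inherits(stations, "station_set"))
  d <- stations$stations
  if (nrow(d) == 0) stop("empty station set", call. = FALSE)
  if (any(d$pm10_mean == 0)) stop("zero PM10 mean", call. = FALSE)
  r <- d$pm25_mean / d$pm10_mean
  list(min = round(min(r), 2), max = round(max(r), 2), mean = mean(r),
       argmin = d$station_id[which.min(r)],
       argmax = d$station_id[which.max(r)],
       ratios = r)
}
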