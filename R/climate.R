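#' Baseline climate stack
#'
#' @param temperature mean annual temperature raster (degrees C).
#' @param precip_wet,precip_dry wet-season (Oct-Mar) and dry-season
#'   (Apr-Sep) precipitation rasters (mm/month).
#' @param year baseline calendar year.
#' @return object of class `climate_stack`.
#' @export
climate_stack <- function(temperature, precip_wet, precip_dry,
                          year = 2010L) {
  stop_if_misaligned(temperature, precip_wet, "climate layers")
  stop_if_misaligned(temperature, precip_dry, "climate layers")
  if (any(raster_values(precip_wet) < 0) ||
      any(raster_values(precip_dry) < 0))
    stop("precipitation must be non-negative", call. = FALSE)
  structure(list(temperature = temperature, precip_wet = precip_wet,
                 precip_dry = precip_dry, year = as.integer(year)),
            class = "climate_stack")
}

#' Baseline climate of a landscape
#'
#' @param landscape a `landscape`.
#' @param year baseline year.
#' @return a [climate_stack()] built from the landscape's climate layers.
#' @export
baseline_climate <- function(landscape, year = 2010L) {
  climate_stack(landscape$predictors$temperature,
                landscape$predictors$precip_wet,
                landscape$predictors$precip_dry, year = year)
}

#' Scenario anomaly schedule
#'
#' A set of epochs with per-epoch delta rasters: additive for temperature
#' (degrees C) and multiplicative for precipitation (per cent of
#' baseline). The first epoch must carry no change (0 degrees C, 100%).
#'
#' @param scenario label, e.g. `"ref"` or `"pol"`.
#' @param epochs strictly increasing years.
#' @param temp list of temperature-delta rasters, one per epoch.
#' @param precip_wet,precip_dry lists of per-cent precipitation deltas.
#' @return object of class `anomaly_schedule`.
#' @export
anomaly_schedule <- function(scenario, epochs, temp, precip_wet,
                             precip_dry) {
  stopifnot(length(epochs) >= 2, all(diff(epochs) > 0),
            length(temp) == length(epochs),
            length(precip_wet) == length(epochs),
            length(precip_dry) == length(epochs))
  if (max(abs(raster_values(temp[[1]]))) > 1e-9 ||
      max(abs(raster_values(precip_wet[[1]]) - 100)) > 1e-9 ||
      max(abs(raster_values(precip_dry[[1]]) - 100)) > 1e-9)
    stop("first epoch of an anomaly schedule must carry no change",
         call. = FALSE)
  structure(list(scenario = scenario, epochs = epochs, temp = temp,
                 precip_wet = precip_wet, precip_dry = precip_dry),
            class = "anomaly_schedule")
}

interp_epoch <- function(layers, epochs, year) {
  if (year <= epochs[1]) return(raster_values(layers[[1]]))
  j <- findInterval(year, epochs)
  if (j >= length(epochs)) return(raster_values(layers[[length(epochs)]]))
  w <- (year - epochs[j]) / (epochs[j + 1] - epochs[j])
  (1 - w) * raster_values(layers[[j]]) + w * raster_values(layers[[j + 1]])
}

#' Projected climate at a given year
#'
#' Applies the scenario anomalies to the baseline climate: temperature adds
#' the delta, precipitation multiplies by the per-cent delta / 100. Deltas
#' are interpolated linearly between epochs and reproduce each epoch
#' exactly; requesting a year outside `[baseline year, last epoch]` is an
#' error (no extrapolation).
#'
#' @param baseline a [climate_stack()].
#' @param schedule an [anomaly_schedule()].
#' @param year calendar year.
#' @return a `climate_stack` for `year`.
#' @export
climate_at <- function(baseline, schedule, year) {
  stopifnot(inherits(baseline, "climate_stack"),
            inherits(schedule, "anomaly_schedule"))
  last <- schedule$epochs[length(schedule$epochs)]
  if (year < baseline$year || year > last)
    stop(sprintf("year %s outside the projectable range [%d, %d]",
                 format(year), baseline$year, last), call. = FALSE)
  cs <- attr(baseline$temperature, "cellsize")
  gr <- function(m) grid_raster(m, cellsize = cs)
  dt <- interp_epoch(schedule$temp, schedule$epochs, year)
  fw <- interp_epoch(schedule$precip_wet, schedule$epochs, year) / 100
  fd <- interp_epoch(schedule$precip_dry, schedule$epochs, year) / 100
  climate_stack(gr(raster_values(baseline$temperature) + dt),
                gr(pmax(raster_values(baseline$precip_wet) * fw, 0)),
                gr(pmax(raster_values(baseline$precip_dry) * fd, 0)),
                year = as.integer(year))
}

#' Observed climate range of a baseline stack
#'
#' @param baseline a `climate_stack`.
#' @return named list of `c(min, max)` per variable.
#' @export
observed_climate_range <- function(baseline) {
  rng <- function(x) range(raster_values(x))
  list(temperature = rng(baseline$temperature),
       precip_wet = rng(baseline$precip_wet),
       precip_dry = rng(baseline$precip_dry))
}

#' Flag climatically novel cells in a projection
#'
#' Marks cells where any projected variable falls outside its observed
#' range, and reports the per-variable exceedance magnitude (positive above
#' the maximum, negative below the minimum, zero inside the range).
#' Predictions in novel cells are extrapolations of the fitted response
#' surfaces and should be interpreted with caution.
#'
#' @param projected a `climate_stack`.
#' @param observed_range named list of `c(min, max)` per variable, as from
#'   [observed_climate_range()].
#' @return list with `novel` (logical `grid_raster`) and `exceedance`
#'   (list of `grid_raster`s per variable).
#' @export
flag_novel_climate <- function(projected, observed_range) {
  stopifnot(inherits(projected, "climate_stack"))
  cs <- attr(projected$temperature, "cellsize")
  exceed <- list()
  novel <- NULL
  for (v in c("temperature", "precip_wet", "precip_dry")) {
    r <- observed_range[[v]]
    if (is.null(r) || !all(is.finite(r)))
      stop(sprintf("observed range for '%s' must be finite", v),
           call. = FALSE)
    x <- raster_values(projected[[v]])
    e <- pmax(x - r[2], 0) + pmin(x - r[1], 0)
    exceed[[v]] <- grid_raster(e, cellsize = cs)
    novel <- if (is.null(novel)) e != 0 else novel | (e != 0)
  }
  list(novel = grid_raster(novel * 1L, cellsize = cs),
       exceedance = exceed)
}
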