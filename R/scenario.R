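#' Nest-to-density conversion parameters
#'
#' Constants of the allometric conversion from an aerial nest-count index
#' to orangutan density: `density = exp(intercept + slope * ln(A)) /
#' (p * r * t)` with `A` nests per km of aerial transect, `p` the
#' proportion of nest-building individuals, `r` the daily nest production
#' rate and `t` the nest decay time in days.
#'
#' @param intercept,slope log-log regression constants (4.730, 0.980).
#' @param p proportion of nest-building individuals (0.9).
#' @param r daily nest production rate (1.084 nests/day).
#' @param t nest decay time (286.3 days).
#' @return object of class `density_params`.
#' @export
density_params <- function(intercept = 4.730, slope = 0.980, p = 0.9,
                           r = 1.084, t = 286.3) {
  stopifnot(intercept > 0, slope > 0, p > 0, r > 0, t > 0)
  structure(list(intercept = intercept, slope = slope, p = p, r = r,
                 t = t), class = "density_params")
}

#' Convert a nest index to orangutan density
#'
#' `Dou = exp(intercept + slope * ln(Ai)) / (p * r * t)` for `Ai > 0`; the
#' conversion is extended continuously with `Dou = 0` at `Ai = 0` (the
#' power law tends to zero from above). Strictly increasing and exactly
#' power-law on `(0, Inf)`.
#'
#' @param Ai nests per km of aerial transect (non-negative, vectorized).
#' @param params a [density_params()].
#' @return orangutan density, individuals per km^2.
#' @export
nests_to_density <- function(Ai, params = density_params()) {
  if (any(Ai < 0)) stop("Ai must be non-negative", call. = FALSE)
  out <- numeric(length(Ai))
  pos <- Ai > 0
  out[pos] <- exp(params$intercept + params$slope * log(Ai[pos])) /
    (params$p * params$r * params$t)
  out
}

#' The four intervention scenarios
#'
#' Maps a scenario name to its sustainable-forest-management policy and
#' climate-mitigation pathway: No Intervention (current SFM, unabated
#' climate change), Habitat Intervention (SFM in all reserves, unabated),
#' Climate Intervention (current SFM, stabilization policy) and Combined
#' Intervention (SFM in all reserves, stabilization policy).
#'
#' @param name one of `"No Intervention"`, `"Habitat Intervention"`,
#'   `"Climate Intervention"`, `"Combined Intervention"`.
#' @return object of class `scenario_spec` with `name`, `sfm_policy`
#'   (`"current"`/`"all"`), `climate` (`"ref"`/`"pol"`).
#' @export
scenario_spec <- function(name = c("No Intervention",
                                   "Habitat Intervention",
                                   "Climate Intervention",
                                   "Combined Intervention")) {
  name <- match.arg(name)
  sfm <- if (name %in% c("Habitat Intervention", "Combined Intervention"))
    "all" else "current"
  climate <- if (name %in% c("Climate Intervention",
                             "Combined Intervention")) "pol" else "ref"
  structure(list(name = name, sfm_policy = sfm, climate = climate),
            class = "scenario_spec")
}

#' Rebuild the predictor stack for a projected year
#'
#' Refreshes the dynamic layers: forest/degraded/mangrove indicators from
#' the current land-cover state and the three climate layers from the
#' projected climate; all static layers (terrain, distances, protection)
#' pass through unchanged. Idempotent for an unchanged state.
#'
#' @param landscape the fitting `landscape` (static layers, geometry).
#' @param landcover `grid_raster` of current class codes.
#' @param climate a `climate_stack` for the year.
#' @return named list of override layers suitable for
#'   [predictor_matrix()] / [predict_hurdle()].
#' @export
rebuild_predictors <- function(landscape, landcover, climate) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(climate, "climate_stack"))
  lc <- raster_values(landcover)
  need <- c("forest", "degraded", "mangrove")
  miss <- setdiff(need, landscape$classes)
  if (length(miss))
    stop(sprintf("land-cover legend lacks class(es): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  cs <- landscape$cellsize
  gr <- function(m) grid_raster(m, cellsize = cs)
  ind <- function(cls) gr((lc == match(cls, landscape$classes)) * 1)
  list(forest = ind("forest"), degraded = ind("degraded"),
       mangrove = ind("mangrove"),
       temperature = climate$temperature,
       precip_wet = climate$precip_wet,
       precip_dry = climate$precip_dry)
}

#' Project a scenario to an abundance trajectory
#'
#' For every simulated year: rebuild the predictor stack from the
#' land-cover state and projected climate, predict the expected nest count
#' per cell with the hurdle model, convert the cell count to a per-km
#' transect index (dividing by the transect length one survey line
#' contributes to a cell, by default the cell side length), convert to
#' density with the allometric formula and multiply by cell area to get
#' cell abundance. Totals and percentage change relative to the first year
#' are recorded.
#'
#' @param model fitted `hurdle_model`.
#' @param spec a [scenario_spec()].
#' @param landseries a `landcover_series` run under the scenario's SFM
#'   policy.
#' @param schedule an `anomaly_schedule` for the scenario's climate
#'   pathway.
#' @param baseline a `climate_stack`.
#' @param landscape the fitting `landscape`.
#' @param params a [density_params()].
#' @param transect_km_per_cell km of transect per traversed cell used to
#'   convert a cell count to nests/km (defaults to the cell size).
#' @param keep_rasters store the abundance raster of every year (otherwise
#'   first and last only).
#' @return object of class `scenario_projection`: `trajectory` (data.frame
#'   `year`, `total`, `pct_change`), `abundance` (list of rasters),
#'   `novelty` (per-year count of climatically novel cells), `spec`.
#' @export
project_scenario <- function(model, spec, landseries, schedule, baseline,
                             landscape, params = density_params(),
                             transect_km_per_cell = landscape$cellsize,
                             keep_rasters = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(landseries, "landcover_series"))
  years <- landseries$years
  have_states <- names(landseries$states)
  cell_area <- landscape$cellsize^2
  obs_range <- observed_climate_range(baseline)
  totals <- numeric(length(years))
  novel_cells <- integer(length(years))
  rasters <- list()
  lc_current <- landseries$states[[1]]
  for (i in seq_along(years)) {
    yr <- years[i]
    key <- as.character(yr)
    if (key %in% have_states) lc_current <- landseries$states[[key]]
    clim <- climate_at(baseline, schedule, yr)
    ov <- rebuild_predictors(landscape, lc_current, clim)
    counts <- predict_hurdle(model, landscape, overrides = ov)
    ai <- raster_values(counts) / transect_km_per_cell
    dens <- matrix(nests_to_density(as.vector(ai), params), nrow(ai),
                   ncol(ai))
    abun <- dens * cell_area
    totals[i] <- sum(abun)
    novel_cells[i] <- sum(raster_values(flag_novel_climate(
      clim, obs_range)$novel))
    if (keep_rasters || i == 1L || i == length(years))
      rasters[[key]] <- grid_raster(abun, cellsize = landscape$cellsize)
  }
  structure(list(
    trajectory = data.frame(year = years, total = totals,
                            pct_change = 100 * (totals / totals[1] - 1)),
    abundance = rasters,
    novelty = data.frame(year = years, novel_cells = novel_cells),
    spec = spec), class = "scenario_projection")
}

#' Compare scenario projections
#'
#' @param projections named list of `scenario_projection`s on the same
#'   grid and years.
#' @param at_years years at which to tabulate percentage change (defaults
#'   to the common final year).
#' @return data.frame with one row per scenario and year: `scenario`,
#'   `year`, `total`, `pct_change`.
#' @export
compare_scenarios <- function(projections, at_years = NULL) {
  stopifnot(length(projections) >= 2)
  yrs <- lapply(projections, function(p) p$trajectory$year)
  if (!all(vapply(yrs, function(y) identical(y, yrs[[1]]), logical(1))))
    stop("projections cover different year ranges", call. = FALSE)
  dims <- lapply(projections, function(p) dim(p$abundance[[1]]))
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    stop("projections are on different grids", call. = FALSE)
  if (is.null(at_years)) at_years <- max(yrs[[1]])
  out <- list()
  for (nm in names(projections)) {
    tr <- projections[[nm]]$trajectory
    sel <- tr[tr$year %in% at_years, , drop = FALSE]
    out[[nm]] <- data.frame(scenario = projections[[nm]]$spec$name,
                            year = sel$year, total = sel$total,
                            pct_change = sel$pct_change)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
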