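#' Configuration for a synthetic survey landscape
#'
#' Defines the grid, the land-cover legend, reserve layout, the true hurdle
#' response surfaces (logistic presence x log-linear expected count over
#' standardized predictors) and the true annual land-cover transition matrix
#' used to generate two-epoch land-cover pairs. The defaults describe a
#' Sabah-like study system: five land-cover classes dominated by forest,
#' roughly 1.2% of forest converted per year, about a third of the area in
#' commercial forest reserves of which a fifth is under sustainable forest
#' management (SFM), and presence/abundance driven most strongly by forest
#' cover, terrain and distance to roads.
#'
#' Coefficients act on z-scored predictors, so their magnitudes are
#' comparable across predictors; a coefficient of 1 moves the linear
#' predictor one unit per standard deviation of that predictor.
#'
#' @param grid_shape integer (rows, cols).
#' @param cell_size cell side length in km.
#' @param seed integer RNG seed.
#' @param landcover_classes ordered class labels; the order is the tie-break
#'   order used throughout the land-cover simulator.
#' @param reserve_fraction approximate proportion of cells inside forest
#'   reserves.
#' @param sfm_fraction proportion of reserves (by count) under SFM at t0.
#' @param n_reserves number of rectangular reserve blocks.
#' @param kernel_width smoothing kernel width (cells) of the Gaussian random
#'   fields used for terrain and climate.
#' @param presence_coefficients,abundance_coefficients named numeric vectors
#'   of true effects on the logit of presence and the log expected count.
#' @param presence_intercept,abundance_intercept intercepts of the two true
#'   linear predictors.
#' @param presence_interaction,abundance_interaction optional
#'   `list(vars = c("a", "b"), coef = x)` adding a product term of two
#'   z-scored predictors to the respective linear predictor.
#' @param transition_truth K x K annual row-stochastic matrix over
#'   `landcover_classes` (rows = source class).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(45, 45),
                             cell_size = 2.5,
                             seed = 1L,
                             landcover_classes = c("forest", "degraded",
                                                   "mangrove", "cleared",
                                                   "water"),
                             reserve_fraction = 0.3,
                             sfm_fraction = 0.2,
                             n_reserves = 6L,
                             kernel_width = 4,
                             presence_coefficients = c(forest = 1.5,
                                                       roaddist = 1.0,
                                                       temperature = 0.8,
                                                       elevation = -1.0),
                             abundance_coefficients = c(elevation = -1.0,
                                                        popdist = 0.8,
                                                        roaddist = 0.6,
                                                        slope = -0.5,
                                                        forest = 0.8),
                             presence_intercept = 0,
                             abundance_intercept = 1.2,
                             presence_interaction = NULL,
                             abundance_interaction = NULL,
                             transition_truth = NULL) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 4),
            cell_size > 0, n_reserves >= 1,
            !anyDuplicated(landcover_classes),
            reserve_fraction >= 0, reserve_fraction < 1,
            sfm_fraction >= 0, sfm_fraction <= 1)
  k <- length(landcover_classes)
  if (is.null(transition_truth)) {
    transition_truth <- diag(k)
    dimnames(transition_truth) <- list(landcover_classes, landcover_classes)
    # ~1.2% pa forest conversion, degraded land slowly cleared, mangrove
    # nearly stable, cleared and water absorbing
    transition_truth["forest", "forest"] <- 0.988
    transition_truth["forest", "degraded"] <- 0.009
    transition_truth["forest", "cleared"] <- 0.003
    transition_truth["degraded", "degraded"] <- 0.985
    transition_truth["degraded", "cleared"] <- 0.015
    transition_truth["mangrove", "mangrove"] <- 0.998
    transition_truth["mangrove", "degraded"] <- 0.002
  }
  check_row_stochastic(transition_truth, tol = 1e-12,
                       what = "transition_truth")
  structure(list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
                 seed = as.integer(seed),
                 landcover_classes = landcover_classes,
                 reserve_fraction = reserve_fraction,
                 sfm_fraction = sfm_fraction,
                 n_reserves = as.integer(n_reserves),
                 kernel_width = kernel_width,
                 presence_coefficients = presence_coefficients,
                 abundance_coefficients = abundance_coefficients,
                 presence_intercept = presence_intercept,
                 abundance_intercept = abundance_intercept,
                 presence_interaction = presence_interaction,
                 abundance_interaction = abundance_interaction,
                 transition_truth = transition_truth),
            class = "synthetic_config")
}

check_row_stochastic <- function(m, tol = 1e-9, what = "transition matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  if (any(m < -tol) || any(m > 1 + tol))
    stop(sprintf("%s has entries outside [0, 1]", what), call. = FALSE)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("%s rows must sum to 1 (max deviation %.3g)", what,
                 max(abs(rs - 1))), call. = FALSE)
  invisible(TRUE)
}

# --- smooth random fields --------------------------------------------------

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

smooth_axis <- function(m, kernel, along = c("row", "col")) {
  along <- match.arg(along)
  half <- (length(kernel) - 1L) / 2L
  num <- matrix(0, nrow(m), ncol(m)); den <- num
  for (j in seq_along(kernel)) {
    off <- j - 1L - half
    s <- if (along == "row") shift_mat(m, off, 0L) else shift_mat(m, 0L, off)
    w <- kernel[j]
    ok <- !is.na(s)
    num[ok] <- num[ok] + w * s[ok]
    den[ok] <- den[ok] + w
  }
  num / den
}

# Standardized Gaussian random field: white noise convolved with a separable
# Gaussian kernel (edge-renormalized), then z-scored over the grid.
gaussian_field <- function(nr, nc, width) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (width > 0) {
    x <- seq(-ceiling(3 * width), ceiling(3 * width))
    k <- stats::dnorm(x, sd = width)
    z <- smooth_axis(smooth_axis(z, k, "row"), k, "col")
  }
  (z - mean(z)) / stats::sd(z)
}

# Euclidean distance (km, cell centres) from every cell to the nearest
# feature cell.
distance_to <- function(mask, cellsize) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("distance_to: empty feature mask", call. = FALSE)
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  d2 <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(idx))) {
    di <- (rr - idx[i, 1])^2 + (cc - idx[i, 2])^2
    d2 <- pmin(d2, di)
  }
  sqrt(d2) * cellsize
}

zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(v * 0)
  (v - mean(v)) / s
}

#' Names of the predictor layers a landscape provides
#'
#' @return character vector in canonical column order.
#' @export
predictor_names <- function() {
  c("popdist", "roaddist", "riverdist", "protectarea", "elevation", "slope",
    "forest", "degraded", "mangrove", "temperature", "precip_wet",
    "precip_dry")
}

#' Generate a synthetic landscape with known hurdle response surfaces
#'
#' Builds an aligned stack of predictor rasters (terrain from a smoothed
#' Gaussian random field, Euclidean distances to randomly placed roads,
#' rivers and settlements, indicator layers from an initial land-cover map,
#' climate fields), reserve/SFM/strictly-protected masks, and the two true
#' response surfaces: probability of presence (logistic in the z-scored
#' predictors) and expected nest count given presence (log-linear).
#'
#' @param config a [synthetic_config()].
#' @return list with elements `landscape` (class `landscape`) and `truth`
#'   (class `truth_surfaces` with rasters `presence_probability` and
#'   `expected_count`).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- config$cell_size
  gr <- function(m) grid_raster(m, cellsize = cs)

  elev_field <- gaussian_field(nr, nc, config$kernel_width)
  elevation <- 250 + 180 * elev_field
  elevation[elevation < 0] <- 0

  # slope: gradient magnitude of elevation (degrees), central differences
  dx <- (shift_mat(elevation, 0L, 1L) - shift_mat(elevation, 0L, -1L)) /
    (2 * cs * 1000)
  dy <- (shift_mat(elevation, 1L, 0L) - shift_mat(elevation, -1L, 0L)) /
    (2 * cs * 1000)
  dx[is.na(dx)] <- 0; dy[is.na(dy)] <- 0
  slope <- atan(sqrt(dx^2 + dy^2)) * 180 / pi

  # linear features: roads (N-S and E-W lines), rivers (meandering E-W
  # lines), settlements (points)
  road_mask <- matrix(FALSE, nr, nc)
  road_mask[, sample.int(nc, 2)] <- TRUE
  road_mask[sample.int(nr, 1), ] <- TRUE
  river_mask <- matrix(FALSE, nr, nc)
  for (r0 in sample.int(nr, 2)) {
    jitter <- round(cumsum(stats::rnorm(nc, 0, 0.6)))
    rows <- pmin(pmax(r0 + jitter, 1), nr)
    river_mask[cbind(rows, seq_len(nc))] <- TRUE
  }
  settle_mask <- matrix(FALSE, nr, nc)
  settle_mask[cbind(sample.int(nr, 3), sample.int(nc, 3))] <- TRUE

  roaddist <- distance_to(road_mask, cs)
  riverdist <- distance_to(river_mask, cs)
  popdist <- distance_to(settle_mask, cs)

  # reserves: rectangular blocks totalling ~reserve_fraction of the grid
  reserve_id <- matrix(0L, nr, nc)
  target <- config$reserve_fraction * nr * nc
  per_block <- target / config$n_reserves
  side <- max(2L, round(sqrt(per_block)))
  for (b in seq_len(config$n_reserves)) {
    r0 <- sample.int(max(1L, nr - side), 1)
    c0 <- sample.int(max(1L, nc - side), 1)
    rows <- r0:min(nr, r0 + side - 1L); cols <- c0:min(nc, c0 + side - 1L)
    blk <- reserve_id[rows, cols]
    blk[blk == 0L] <- b
    reserve_id[rows, cols] <- blk
  }
  n_sfm <- max(1L, round(config$sfm_fraction * config$n_reserves))
  sfm_ids <- seq_len(n_sfm)
  sfm_mask <- matrix(reserve_id %in% sfm_ids & reserve_id > 0L, nr, nc)

  # one strictly protected block outside the reserves
  strict_mask <- matrix(FALSE, nr, nc)
  side_s <- max(2L, round(sqrt(0.04 * nr * nc)))
  for (try in 1:50) {
    r0 <- sample.int(max(1L, nr - side_s), 1)
    c0 <- sample.int(max(1L, nc - side_s), 1)
    rows <- r0:min(nr, r0 + side_s - 1L)
    cols <- c0:min(nc, c0 + side_s - 1L)
    if (all(reserve_id[rows, cols] == 0L)) {
      strict_mask[rows, cols] <- TRUE
      break
    }
  }

  # initial land cover from terrain and features
  classes <- config$landcover_classes
  lc <- matrix(match("forest", classes), nr, nc)
  qe <- stats::quantile(elevation, c(0.03, 0.08))
  lc[elevation <= qe[1]] <- match("water", classes)
  lc[elevation > qe[1] & elevation <= qe[2] & riverdist < 4 * cs] <-
    match("mangrove", classes)
  cleared_zone <- popdist < 1.5 * cs & lc == match("forest", classes)
  lc[cleared_zone] <- match("cleared", classes)
  degr_zone <- roaddist < 1.2 * cs & reserve_id == 0L & !strict_mask &
    lc == match("forest", classes)
  lc[degr_zone] <- match("degraded", classes)

  temperature <- 27 - 0.0055 * (elevation - min(elevation)) +
    0.3 * gaussian_field(nr, nc, config$kernel_width)
  precip_wet <- pmax(260 + 40 * gaussian_field(nr, nc,
                                               config$kernel_width), 0)
  precip_dry <- pmax(130 + 25 * gaussian_field(nr, nc,
                                               config$kernel_width), 0)

  predictors <- list(
    popdist = gr(popdist), roaddist = gr(roaddist),
    riverdist = gr(riverdist),
    protectarea = gr(strict_mask * 1), elevation = gr(elevation),
    slope = gr(slope),
    forest = gr((lc == match("forest", classes)) * 1),
    degraded = gr((lc == match("degraded", classes)) * 1),
    mangrove = gr((lc == match("mangrove", classes)) * 1),
    temperature = gr(temperature), precip_wet = gr(precip_wet),
    precip_dry = gr(precip_dry))

  landscape <- structure(list(predictors = predictors,
                              landcover = gr(lc), classes = classes,
                              reserve_id = gr(reserve_id),
                              sfm_mask = gr(sfm_mask * 1L),
                              strict_mask = gr(strict_mask * 1L),
                              cellsize = cs, config = config),
                         class = "landscape")
  truth <- truth_surfaces(landscape, config)
  list(landscape = landscape, truth = truth)
}

lin_pred <- function(z, coefs, intercept, interaction) {
  eta <- rep(intercept, nrow(z))
  for (nm in names(coefs)) {
    if (!nm %in% colnames(z))
      stop(sprintf("unknown predictor in coefficients: '%s'", nm),
           call. = FALSE)
    eta <- eta + coefs[[nm]] * z[, nm]
  }
  if (!is.null(interaction))
    eta <- eta + interaction$coef * z[, interaction$vars[1]] *
      z[, interaction$vars[2]]
  eta
}

truth_surfaces <- function(landscape, config) {
  x <- predictor_matrix(landscape)
  z <- apply(x, 2, zscore)
  eta_p <- lin_pred(z, config$presence_coefficients,
                    config$presence_intercept,
                    config$presence_interaction)
  eta_a <- lin_pred(z, config$abundance_coefficients,
                    config$abundance_intercept,
                    config$abundance_interaction)
  dims <- dim(landscape$landcover)
  gr <- function(v) grid_raster(matrix(v, dims[1], dims[2]),
                                cellsize = landscape$cellsize)
  structure(list(presence_probability = gr(stats::plogis(eta_p)),
                 expected_count = gr(exp(eta_a))),
            class = "truth_surfaces")
}

#' Predictor matrix of a landscape
#'
#' Flattens the landscape's predictor stack to an n-cells x p matrix in
#' canonical column order (column-major cell order). Used both when
#' assembling the modelling dataset and when predicting over the grid.
#'
#' @param landscape a `landscape`.
#' @param overrides optional named list of `grid_raster`/matrix layers that
#'   replace the stored ones (dynamic land-cover indicators, projected
#'   climate).
#' @return numeric matrix with `predictor_names()` columns.
#' @export
predictor_matrix <- function(landscape, overrides = NULL) {
  layers <- landscape$predictors
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      stop_if_misaligned(layers[[1]], overrides[[nm]], "predictor layers")
      layers[[nm]] <- overrides[[nm]]
    }
  }
  miss <- setdiff(predictor_names(), names(layers))
  if (length(miss))
    stop(sprintf("missing predictor layer(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  do.call(cbind,
          lapply(layers[predictor_names()], function(l) as.vector(
            raster_values(l))))
}

#' Simulate an aerial nest-count survey over a landscape
#'
#' Transects are straight north-south lines at a fixed spacing. Every cell
#' crossed by a transect in a survey year yields one record: a Bernoulli
#' presence draw at the cell's true presence probability, and, if present, a
#' Poisson count at the cell's true expected count. A configurable fraction
#' of transects is restricted to forest-reserve cells, reproducing the
#' survey bias towards reserves that motivates pseudoabsence sampling.
#'
#' @param landscape,truth output of [generate_landscape()].
#' @param transect_spacing spacing between transects in km (>= cell size).
#' @param repeat_years integer vector of survey years; each transect is
#'   surveyed independently in every year listed.
#' @param reserve_bias proportion of transects restricted to reserve cells.
#' @param seed integer RNG seed.
#' @return object of class `nest_survey`: list with `records` (data.frame
#'   `transect_id`, `year`, `row`, `col`, `count`) and an empty
#'   `pseudoabsences` data.frame to be filled by
#'   [sample_pseudoabsences()].
#' @export
generate_survey <- function(landscape, truth, transect_spacing = 5,
                            repeat_years = c(2001:2003, 2007, 2009:2010),
                            reserve_bias = 0.5, seed = 1L) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(truth, "truth_surfaces"),
            reserve_bias >= 0, reserve_bias <= 1)
  cs <- landscape$cellsize
  if (transect_spacing < cs)
    stop("transect_spacing must be at least the cell size", call. = FALSE)
  nr <- nrow(landscape$landcover); nc <- ncol(landscape$landcover)
  step <- max(1L, round(transect_spacing / cs))
  cols <- seq(1L, nc, by = step)
  if (length(cols) == 0)
    stop("transect spacing wider than the grid: no transects intersect it",
         call. = FALSE)
  set.seed(seed)
  n_res_transects <- round(reserve_bias * length(cols))
  restricted <- rep(FALSE, length(cols))
  if (n_res_transects > 0)
    restricted[sample.int(length(cols), n_res_transects)] <- TRUE
  p <- raster_values(truth$presence_probability)
  mu <- raster_values(truth$expected_count)
  res_id <- raster_values(landscape$reserve_id)
  recs <- list()
  for (ti in seq_along(cols)) {
    cc <- cols[ti]
    rows <- seq_len(nr)
    if (restricted[ti]) rows <- rows[res_id[rows, cc] > 0]
    if (length(rows) == 0) next
    for (yr in repeat_years) {
      pres <- stats::rbinom(length(rows), 1L, p[cbind(rows, cc)])
      cnt <- ifelse(pres == 1L,
                    stats::rpois(length(rows), mu[cbind(rows, cc)]), 0L)
      recs[[length(recs) + 1L]] <-
        data.frame(transect_id = ti, year = yr, row = rows, col = cc,
                   count = as.integer(cnt))
    }
  }
  if (length(recs) == 0)
    stop("survey intersected no cells", call. = FALSE)
  structure(list(records = do.call(rbind, recs),
                 pseudoabsences = data.frame(row = integer(),
                                             col = integer())),
            class = "nest_survey")
}

#' Generate an observed two-epoch land-cover pair
#'
#' Applies the interval transition kernel (the annual truth matrix raised to
#' `interval_years`) cell-wise with independent categorical draws, to
#' produce the kind of two-date land-cover observation from which the
#' simulator estimates transition rates. Strictly protected cells are held
#' fixed, mirroring the exclusion of such areas from rate estimation.
#'
#' @param landscape a `landscape` (epoch-0 land cover is its `landcover`).
#' @param transition_truth annual K x K row-stochastic matrix; defaults to
#'   the one in the landscape's config.
#' @param interval_years integer >= 1.
#' @param seed integer RNG seed.
#' @return list with `raster_t0` and `raster_t1` (`grid_raster` of class
#'   codes).
#' @export
generate_two_epoch_landcover <- function(landscape, transition_truth = NULL,
                                         interval_years = 10L, seed = 1L) {
  stopifnot(inherits(landscape, "landscape"), interval_years >= 1)
  if (is.null(transition_truth))
    transition_truth <- landscape$config$transition_truth
  check_row_stochastic(transition_truth, tol = 1e-12,
                       what = "transition_truth")
  kernel <- mat_power(transition_truth, interval_years)
  set.seed(seed)
  lc0 <- raster_values(landscape$landcover)
  strict <- raster_values(landscape$strict_mask) > 0
  lc1 <- lc0
  k <- nrow(kernel)
  for (c0 in seq_len(k)) {
    cells <- which(lc0 == c0 & !strict)
    if (length(cells) == 0) next
    lc1[cells] <- sample.int(k, length(cells), replace = TRUE,
                             prob = kernel[c0, ])
  }
  list(raster_t0 = landscape$landcover,
       raster_t1 = grid_raster(lc1, cellsize = landscape$cellsize))
}

mat_power <- function(m, n) {
  out <- diag(nrow(m))
  for (i in seq_len(n)) out <- out %*% m
  dimnames(out) <- dimnames(m)
  out
}

#' Generate a scenario climate-anomaly schedule
#'
#' Produces smooth additive temperature deltas (degrees C) and multiplicative
#' precipitation deltas (per cent of baseline) at a set of epochs, with a
#' configurable end-of-century state-mean temperature increase. The spatial
#' pattern is a centred Gaussian random field, so the state mean of the 2100
#' temperature delta equals the configured magnitude exactly; precipitation
#' stays close to 100% ("relatively stable") with small smooth departures.
#' The first epoch carries zero change by construction.
#'
#' @param landscape a `landscape` (fixes grid geometry).
#' @param epochs strictly increasing years; the first is the baseline.
#' @param scenario `"ref"` (no-climate-policy, default +2.5 C by the last
#'   epoch), `"pol"` (stabilization policy, +1.2 C) or `"none"` (0 C).
#' @param seed integer RNG seed.
#' @param temp_end optional override of the end-of-century state-mean
#'   temperature delta in degrees C.
#' @param precip_amp amplitude (percentage points) of the smooth
#'   precipitation departures at the last epoch.
#' @return object of class `anomaly_schedule` (see [climate_at()]).
#' @export
generate_climate_deltas <- function(landscape,
                                    epochs = c(2010, 2041, 2071, 2100),
                                    scenario = c("ref", "pol", "none"),
                                    seed = 1L, temp_end = NULL,
                                    precip_amp = 3) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(landscape, "landscape"), length(epochs) >= 2,
            all(diff(epochs) > 0))
  if (is.null(temp_end))
    temp_end <- switch(scenario, ref = 2.5, pol = 1.2, none = 0)
  if (missing(precip_amp) && scenario == "none") precip_amp <- 0
  set.seed(seed)
  nr <- nrow(landscape$landcover); nc <- ncol(landscape$landcover)
  w <- landscape$config$kernel_width %||% 4
  pat_t <- gaussian_field(nr, nc, w); pat_t <- pat_t - mean(pat_t)
  pat_w <- gaussian_field(nr, nc, w); pat_w <- pat_w - mean(pat_w)
  pat_d <- gaussian_field(nr, nc, w); pat_d <- pat_d - mean(pat_d)
  gr <- function(m) grid_raster(m, cellsize = landscape$cellsize)
  frac <- (epochs - epochs[1]) / (epochs[length(epochs)] - epochs[1])
  temp <- lapply(frac, function(f) gr(f * (temp_end + 0.3 * temp_end *
                                             pat_t)))
  pw <- lapply(frac, function(f) gr(pmax(100 + f * precip_amp * pat_w, 0)))
  pd <- lapply(frac, function(f) gr(pmax(100 + f * precip_amp * pat_d, 0)))
  anomaly_schedule(scenario = scenario, epochs = epochs, temp = temp,
                   precip_wet = pw, precip_dry = pd)
}
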