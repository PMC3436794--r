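# Shared fixtures: one moderate synthetic world and a fast fitting
# configuration, built once per test run. The fast config trades the full
# lr/tc search for a single point with a short tree grid; machinery tests
# do not depend on the size of the search space.

fast_fit_config <- function(seed = 1L) {
  hurdle_fit_config(lr_grid = 0.05, tc_grid = 2L, nt_max = 400L,
                    cv_folds = 5L, seed = seed)
}

shared <- local({
  cfg <- synthetic_config(grid_shape = c(28, 28), seed = 7L)
  gen <- generate_landscape(cfg)
  survey <- generate_survey(gen$landscape, gen$truth, transect_spacing = 5,
                            reserve_bias = 0.3, seed = 8L)
  survey <- sample_pseudoabsences(gen$landscape, survey, 80L, seed = 9L)
  gridded <- aggregate_counts(survey, gen$landscape)
  model <- optimize_hurdle(gridded, fast_fit_config(seed = 7L))
  list(cfg = cfg, landscape = gen$landscape, truth = gen$truth,
       survey = survey, gridded = gridded, model = model)
})

# stand-alone gridded dataset from raw matrices, for machinery tests that
# need full control over the response
make_dataset <- function(x, presence, count) {
  d <- cbind(data.frame(cell_id = seq_len(nrow(x)), row = 1L, col = 1L,
                        mean_count = count, n_records = 1L,
                        source = "observed", presence = presence),
             as.data.frame(x))
  attr(d, "predictors") <- colnames(x)
  class(d) <- c("gridded_dataset", "data.frame")
  d
}

# brute-force Moran's I: explicit double sum over the full weight matrix
moran_brute <- function(m, scheme = "queen") {
  nr <- nrow(m); nc <- ncol(m)
  n <- nr * nc
  coords <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dr <- abs(coords$row[i] - coords$row[j])
      dc <- abs(coords$col[i] - coords$col[j])
      touching <- if (scheme == "queen") dr <= 1 && dc <= 1
      else (dr + dc) == 1
      if (touching) w[i, j] <- 1
    }
  }
  w <- w / rowSums(w)
  x <- as.vector(m)          # column-major, matching coords
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# brute-force maximum sensitivity+specificity threshold
sss_brute <- function(p, y) {
  cand <- sort(unique(p))
  score <- vapply(cand, function(t) {
    pred <- p >= t
    sum(pred & y == 1) / sum(y == 1) + sum(!pred & y == 0) / sum(y == 0)
  }, numeric(1))
  best <- max(score)
  min(cand[score >= best - 1e-12])
}

# minimal hand-built simulation objects for the land-cover stepper
make_state <- function(lc, reserve_id = NULL, sfm = NULL, strict = NULL,
                       classes = c("forest", "degraded"), cellsize = 2.5,
                       year = 2010L) {
  z <- matrix(0L, nrow(lc), ncol(lc))
  structure(list(landcover = grid_raster(lc, cellsize = cellsize),
                 reserve_id = grid_raster(reserve_id %||% z,
                                          cellsize = cellsize),
                 sfm_mask = grid_raster(sfm %||% z, cellsize = cellsize),
                 strict_mask = grid_raster(strict %||% z,
                                           cellsize = cellsize),
                 regen_clock = grid_raster(z, cellsize = cellsize),
                 classes = classes, cellsize = cellsize,
                 year = as.integer(year)),
            class = "land_state")
}

make_vm <- function(vulnerability, target, classes = c("forest",
                                                       "degraded"),
                    cellsize = 2.5) {
  structure(list(vulnerability = grid_raster(vulnerability,
                                             cellsize = cellsize),
                 target_class = grid_raster(target, cellsize = cellsize),
                 classes = classes),
            class = "vulnerability_map")
}

make_tm <- function(annual, classes, interval_years = 10L) {
  structure(list(annual_matrix = annual,
                 interval_matrix = annual, interval_years = interval_years,
                 classes = classes),
            class = "transition_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
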