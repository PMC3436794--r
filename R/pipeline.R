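#' Pipeline configuration
#'
#' Bundles every stage's settings and a master seed from which all
#' stage seeds are derived deterministically (fixed offsets), so a config
#' fully determines the run. Accepts either explicit component configs or
#' the arguments to build them.
#'
#' @param seed master integer seed.
#' @param synthetic a [synthetic_config()].
#' @param fit a [hurdle_fit_config()].
#' @param transect_spacing,repeat_years,reserve_bias survey settings, see
#'   [generate_survey()].
#' @param n_pseudoabsence number of pseudoabsence cells.
#' @param interval_years epoch separation of the observed land-cover pair.
#' @param start_year,end_year projection span.
#' @param epochs climate anomaly epochs.
#' @param regen_years reserve regeneration delay.
#' @param simplify run the backward-elimination comparison after the grid
#'   search (slower; the grid search alone already selects lr/tc/nt).
#' @return object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            fit = hurdle_fit_config(seed = seed),
                            transect_spacing = 5,
                            repeat_years = c(2001:2003, 2007, 2009:2010),
                            reserve_bias = 0.5,
                            n_pseudoabsence = 250L,
                            interval_years = 10L,
                            start_year = 2010L, end_year = 2100L,
                            epochs = c(2010, 2041, 2071, 2100),
                            regen_years = 60L,
                            simplify = FALSE) {
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 fit = fit, transect_spacing = transect_spacing,
                 repeat_years = repeat_years, reserve_bias = reserve_bias,
                 n_pseudoabsence = as.integer(n_pseudoabsence),
                 interval_years = as.integer(interval_years),
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year), epochs = epochs,
                 regen_years = as.integer(regen_years),
                 simplify = isTRUE(simplify)),
            class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' A 32 x 32 grid with a reduced fitting search (single learning rate and
#' tree complexity, trees up to 750, 5 folds) sized so the full four-
#' scenario pipeline runs in a couple of minutes.
#'
#' @param seed master integer seed.
#' @return a [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L) {
  pipeline_config(
    seed = seed,
    synthetic = synthetic_config(grid_shape = c(32, 32), seed = seed),
    fit = hurdle_fit_config(lr_grid = 0.05, tc_grid = 2L, nt_max = 750L,
                            cv_folds = 5L, seed = seed),
    n_pseudoabsence = 120L)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML document override the defaults of
#' [pipeline_config()]; `synthetic` and `fit` sub-maps are passed to their
#' constructors.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  syn <- do.call(synthetic_config,
                 c(y$synthetic %||% list(), list(seed = seed)))
  fit <- do.call(hurdle_fit_config,
                 c(y$fit %||% list(), list(seed = seed)))
  args <- y[setdiff(names(y), c("synthetic", "fit"))]
  do.call(pipeline_config,
          c(args, list(synthetic = syn, fit = fit)))
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes every stage end to end: synthetic landscape and truth surfaces;
#' aerial survey, pseudoabsence sampling and gridding; spatial
#' autocorrelation and correlation screens; hurdle model optimization (and
#' optional simplification); transition estimation from the two-epoch
#' land-cover pair; vulnerability mapping; land-cover simulation under
#' both SFM policies; climate anomaly schedules for both pathways; the
#' four scenario projections; and the scenario comparison table. Artifacts
#' are written under `out_dir` (plain-text rasters, CSV tables, JSON
#' manifest with per-file MD5 hashes and all seeds).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed; `NULL` skips all
#'   file output.
#' @param quiet suppress per-stage messages.
#' @return (invisibly) list with every intermediate object and, when
#'   `out_dir` is given, the `manifest`.
#' @export
run_pipeline <- function(config = demo_pipeline_config(), out_dir = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  say("stage 1/7: synthetic landscape")
  gen <- generate_landscape(config$synthetic)
  landscape <- gen$landscape; truth <- gen$truth

  say("stage 2/7: survey, pseudoabsences, gridding")
  survey <- generate_survey(landscape, truth,
                            transect_spacing = config$transect_spacing,
                            repeat_years = config$repeat_years,
                            reserve_bias = config$reserve_bias,
                            seed = seed + 11L)
  survey <- sample_pseudoabsences(landscape, survey,
                                  config$n_pseudoabsence,
                                  seed = seed + 12L)
  gridded <- aggregate_counts(survey, landscape)
  moran <- local_morans_i(truth$expected_count)
  screen <- screen_predictors(gridded)

  say("stage 3/7: hurdle model (%d rows)", nrow(gridded))
  model <- optimize_hurdle(gridded, config$fit)
  if (config$simplify) model <- simplify_hurdle(model, gridded, config$fit)
  metrics <- evaluate_hurdle(model, gridded)

  say("stage 4/7: land-cover transition and vulnerability")
  epochs_lc <- generate_two_epoch_landcover(
    landscape, interval_years = config$interval_years, seed = seed + 21L)
  tm <- estimate_transition(
    epochs_lc$raster_t0, epochs_lc$raster_t1, landscape$classes,
    interval_years = config$interval_years,
    mask = raster_values(landscape$strict_mask) == 0)
  vm <- fit_vulnerability(landscape, seed = seed + 22L)

  say("stage 5/7: land-cover simulation under both SFM policies")
  series <- list()
  for (policy in c("current", "all")) {
    st <- apply_sfm_policy(land_state(landscape, config$start_year),
                           policy)
    series[[policy]] <- run_landcover(st, tm, vm, config$end_year,
                                      regen_years = config$regen_years)
  }

  say("stage 6/7: climate schedules and scenario projections")
  base_clim <- baseline_climate(landscape, config$start_year)
  schedules <- list(
    ref = generate_climate_deltas(landscape, config$epochs, "ref",
                                  seed = seed + 31L),
    pol = generate_climate_deltas(landscape, config$epochs, "pol",
                                  seed = seed + 31L))
  scen_names <- c("No Intervention", "Habitat Intervention",
                  "Climate Intervention", "Combined Intervention")
  projections <- list()
  for (nm in scen_names) {
    sp <- scenario_spec(nm)
    projections[[nm]] <- project_scenario(
      model, sp, series[[sp$sfm_policy]], schedules[[sp$climate]],
      base_clim, landscape)
  }

  say("stage 7/7: comparison and output")
  comparison <- compare_scenarios(projections,
                                  at_years = c(2041, 2071,
                                               config$end_year))
  result <- list(config = config, landscape = landscape, truth = truth,
                 survey = survey, gridded = gridded, moran = moran,
                 screen = screen, model = model, metrics = metrics,
                 transition = tm, vulnerability = vm, series = series,
                 schedules = schedules, projections = projections,
                 comparison = comparison)
  if (!is.null(out_dir))
    result$manifest <- write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put_raster <- function(r, name) {
    p <- file.path(out_dir, paste0(name, ".asc"))
    write_asc(r, p)
    files <<- c(files, p)
  }
  put_csv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write_csv_plain(df, p)
    files <<- c(files, p)
  }
  put_raster(result$landscape$landcover, "landcover_t0")
  put_raster(result$truth$presence_probability, "truth_presence")
  put_raster(result$truth$expected_count, "truth_expected_count")
  gridded_df <- as.data.frame(result$gridded)
  put_csv(gridded_df, "gridded_dataset")
  put_csv(result$screen, "predictor_screen")
  put_csv(result$model$search, "fit_search")
  put_csv(result$comparison, "scenario_comparison")
  traj <- do.call(rbind, lapply(names(result$projections), function(nm) {
    cbind(scenario = nm, result$projections[[nm]]$trajectory)
  }))
  put_csv(traj, "trajectories")
  for (nm in names(result$projections)) {
    pr <- result$projections[[nm]]
    last <- pr$abundance[[length(pr$abundance)]]
    put_raster(last, paste0("abundance_2100_", gsub("[^A-Za-z]", "_",
                                                    nm)))
  }
  for (policy in names(result$series))
    put_csv(result$series[[policy]]$ledger,
            paste0("landcover_ledger_", policy))
  m_named <- unlist(list(
    auc = result$metrics$auc, kappa = result$metrics$kappa,
    mse = result$metrics$mse, rmpe = result$metrics$rmpe,
    deviance_explained = result$metrics$deviance_explained))
  put_csv(data.frame(metric = names(m_named), value = as.numeric(m_named)),
          "model_metrics")
  hashes <- tools::md5sum(files)
  manifest <- list(seed = result$config$seed,
                   grid_shape = result$config$synthetic$grid_shape,
                   files = lapply(seq_along(files), function(i) {
                     list(path = basename(files[i]),
                          md5 = unname(hashes[i]))
                   }))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  manifest
}
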