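test_that("zero coefficients give a flat presence surface at 0.5", {
  cfg <- synthetic_config(grid_shape = c(12, 12), seed = 3L,
                          presence_coefficients = numeric(),
                          abundance_coefficients = numeric(),
                          presence_intercept = 0)
  gen <- generate_landscape(cfg)
  expect_equal(as.vector(unclass(gen$truth$presence_probability)),
               rep(0.5, 144))
})

test_that("identical seed and config reproduce byte-identical rasters", {
  cfg <- synthetic_config(grid_shape = c(15, 15), seed = 11L)
  g1 <- generate_landscape(cfg)
  g2 <- generate_landscape(cfg)
  f1 <- withr::local_tempfile(fileext = ".asc")
  f2 <- withr::local_tempfile(fileext = ".asc")
  for (nm in names(g1$landscape$predictors)) {
    write_asc(g1$landscape$predictors[[nm]], f1)
    write_asc(g2$landscape$predictors[[nm]], f2)
    expect_identical(readLines(f1), readLines(f2))
  }
  expect_identical(unclass(g1$truth$expected_count),
                   unclass(g2$truth$expected_count))
})

test_that("a strong negative elevation effect shows in the truth surface", {
  cfg <- synthetic_config(grid_shape = c(30, 30), seed = 5L,
                          presence_coefficients = c(elevation = -4),
                          abundance_coefficients = c(elevation = -1))
  gen <- generate_landscape(cfg)
  rho <- cor(as.vector(unclass(gen$landscape$predictors$elevation)),
             as.vector(unclass(gen$truth$presence_probability)),
             method = "spearman")
  expect_lt(rho, -0.9)
})

test_that("all predictor layers share one geometry", {
  ls <- shared$landscape
  for (nm in names(ls$predictors))
    expect_true(same_geometry(ls$predictors[[1]], ls$predictors[[nm]]))
  expect_true(same_geometry(ls$predictors[[1]], ls$landcover))
})

test_that("survey counts are all zero when presence probability is zero", {
  gen <- generate_landscape(synthetic_config(grid_shape = c(12, 12),
                                             seed = 2L))
  truth0 <- gen$truth
  truth0$presence_probability <- grid_raster(matrix(0, 12, 12),
                                             cellsize = 2.5)
  sv <- generate_survey(gen$landscape, truth0, transect_spacing = 2.5,
                        repeat_years = 2001:2002, seed = 4L)
  expect_true(all(sv$records$count == 0))
})

test_that("survey draws have the truth-surface mean (Monte-Carlo)", {
  gen <- generate_landscape(synthetic_config(grid_shape = c(40, 40),
                                             seed = 6L))
  truth <- gen$truth
  truth$presence_probability <- grid_raster(matrix(1, 40, 40),
                                            cellsize = 2.5)
  truth$expected_count <- grid_raster(matrix(4, 40, 40), cellsize = 2.5)
  sv <- generate_survey(gen$landscape, truth, transect_spacing = 2.5,
                        repeat_years = 2001:2002, reserve_bias = 0,
                        seed = 10L)
  n <- nrow(sv$records)
  se <- sqrt(4 / n)
  expect_lt(abs(mean(sv$records$count) - 4), 3 * se)
})

test_that("empirical presence fraction matches the analytic surface mean", {
  gen <- generate_landscape(synthetic_config(grid_shape = c(40, 40),
                                             seed = 12L))
  sv <- generate_survey(gen$landscape, gen$truth, transect_spacing = 2.5,
                        repeat_years = 2001, reserve_bias = 0, seed = 13L)
  p <- unclass(gen$truth$presence_probability)[
    cbind(sv$records$row, sv$records$col)]
  # the latent presence draw is not observable from counts alone;
  # compare the rate of nonzero counts with its analytic expectation
  p_nonzero <- p * (1 - exp(-unclass(gen$truth$expected_count)[
    cbind(sv$records$row, sv$records$col)]))
  frac <- mean(sv$records$count > 0)
  se <- sqrt(sum(p_nonzero * (1 - p_nonzero))) / length(p_nonzero)
  expect_lt(abs(frac - mean(p_nonzero)), 3 * se)
})

test_that("fully reserve-biased surveys only touch reserve cells", {
  sv <- generate_survey(shared$landscape, shared$truth,
                        transect_spacing = 2.5, repeat_years = 2001,
                        reserve_bias = 1, seed = 14L)
  res <- unclass(shared$landscape$reserve_id)
  expect_true(all(res[cbind(sv$records$row, sv$records$col)] > 0))
})

test_that("transect spacing below the cell size is rejected", {
  expect_error(generate_survey(shared$landscape, shared$truth,
                               transect_spacing = 1, seed = 1L),
               "cell size")
})

test_that("identity transition truth leaves land cover unchanged", {
  k <- length(shared$landscape$classes)
  ident <- diag(k)
  dimnames(ident) <- list(shared$landscape$classes,
                          shared$landscape$classes)
  two <- generate_two_epoch_landcover(shared$landscape, ident,
                                      interval_years = 10L, seed = 20L)
  expect_identical(unclass(two$raster_t1), unclass(two$raster_t0))
})

test_that("two-epoch forest loss matches the binomial expectation", {
  classes <- shared$landscape$classes
  k <- length(classes)
  tt <- diag(k)
  dimnames(tt) <- list(classes, classes)
  tt["forest", "forest"] <- 0.9779
  tt["forest", "degraded"] <- 0.0221
  two <- generate_two_epoch_landcover(shared$landscape, tt,
                                      interval_years = 10L, seed = 21L)
  fc <- match("forest", classes)
  strict <- unclass(shared$landscape$strict_mask) > 0
  at_risk <- unclass(two$raster_t0) == fc & !strict
  n <- sum(at_risk)
  lost <- sum(unclass(two$raster_t1)[at_risk] != fc)
  p_loss <- 1 - 0.9779^10
  se <- sqrt(n * p_loss * (1 - p_loss))
  expect_lt(abs(lost - n * p_loss), 3 * se)
  # conservation: class counts still sum to the grid total
  expect_equal(length(unclass(two$raster_t1)),
               sum(table(unclass(two$raster_t1))))
})

test_that("non-row-stochastic transition truth is a configuration error", {
  k <- length(shared$landscape$classes)
  bad <- diag(k) * 0.9
  dimnames(bad) <- list(shared$landscape$classes,
                        shared$landscape$classes)
  expect_error(generate_two_epoch_landcover(shared$landscape, bad,
                                            seed = 1L), "sum to 1")
  expect_error(synthetic_config(transition_truth = bad), "sum to 1")
})

test_that("climate deltas honour scenario magnitude and baseline epoch", {
  sch0 <- generate_climate_deltas(shared$landscape, scenario = "none",
                                  seed = 30L)
  for (i in seq_along(sch0$epochs)) {
    expect_equal(max(abs(unclass(sch0$temp[[i]]))), 0)
    expect_equal(as.vector(unclass(sch0$precip_wet[[i]])),
                 rep(100, length(sch0$precip_wet[[i]])))
  }
  ref <- generate_climate_deltas(shared$landscape, scenario = "ref",
                                 seed = 31L)
  expect_equal(mean(unclass(ref$temp[[length(ref$epochs)]])), 2.5,
               tolerance = 0.05 / 2.5)
  expect_equal(max(abs(unclass(ref$temp[[1]]))), 0)
  pol <- generate_climate_deltas(shared$landscape, scenario = "pol",
                                 seed = 31L)
  expect_equal(mean(unclass(pol$temp[[length(pol$epochs)]])), 1.2,
               tolerance = 0.05 / 1.2)
})
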