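test_that("identical epochs give identity transition matrices", {
  lc <- grid_raster(matrix(sample(1:3, 64, TRUE), 8, 8))
  tm <- estimate_transition(lc, lc, c("forest", "degraded", "cleared"),
                            interval_years = 10L)
  expect_equal(tm$interval_matrix, diag(3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tm$annual_matrix, diag(3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("two-class annualization matches the scalar root", {
  lc0 <- grid_raster(matrix(1L, 10, 10))
  v <- c(rep(2L, 20), rep(1L, 80))
  lc1 <- grid_raster(matrix(v, 10, 10))
  tm <- suppressWarnings(
    estimate_transition(lc0, lc1, c("forest", "degraded"),
                        interval_years = 10L))  # degraded absent at t0
  expect_equal(tm$interval_matrix["forest", "forest"], 0.8)
  expect_equal(tm$annual_matrix["forest", "forest"], 0.8^(1 / 10),
               tolerance = 1e-9)
  expect_equal(tm$annual_matrix["forest", "degraded"], 1 - 0.8^(1 / 10),
               tolerance = 1e-9)
})

test_that("the annual matrix to the interval power reproduces the interval matrix", {
  # realize an interval matrix exactly, from counts with known fractions
  lc0 <- grid_raster(matrix(rep(1:3, each = 500), 50, 30))
  to <- c(rep(1L, 450), rep(2L, 40), rep(3L, 10),
          rep(2L, 470), rep(3L, 30),
          rep(3L, 500))
  lc1 <- grid_raster(matrix(to, 50, 30))
  tm <- estimate_transition(lc0, lc1, c("a", "b", "c"),
                            interval_years = 10L)
  expect_equal(orangsim:::mat_power(tm$annual_matrix, 10),
               tm$interval_matrix, tolerance = 1e-6)
  expect_lt(max(abs(rowSums(tm$annual_matrix) - 1)), 1e-9)
})

test_that("a class absent at t0 gets an identity row with a warning", {
  lc0 <- grid_raster(matrix(1L, 5, 5))
  lc1 <- grid_raster(matrix(1L, 5, 5))
  expect_warning(
    tm <- estimate_transition(lc0, lc1, c("forest", "degraded"),
                              interval_years = 5L),
    "absent")
  expect_equal(tm$interval_matrix["degraded", "degraded"], 1)
})

test_that("vulnerability definition: second-highest membership, earlier-class ties", {
  probs <- rbind(c(0.7, 0.2, 0.1),
                 c(0.5, 0.25, 0.25),   # tie for second place
                 c(0.1, 0.2, 0.7))
  v <- vulnerability_from_probs(probs, c("forest", "degraded", "cleared"))
  expect_equal(v$predicted, c(1L, 1L, 3L))
  expect_equal(v$target, c(2L, 2L, 2L))
  expect_equal(v$vulnerability, c(0.2, 0.25, 0.2))
  expect_true(all(v$target != v$predicted))
  expect_error(vulnerability_from_probs(rbind(c(0.5, 0.2)), c("a", "b")),
               "sum to 1")
})

test_that("perfectly separable classes yield low vulnerability", {
  ls <- shared$landscape
  elev <- unclass(ls$predictors$elevation)
  lc <- grid_raster((elev >= median(elev)) + 1L, cellsize = ls$cellsize)
  vm <- fit_vulnerability(ls, landcover = lc, seed = 17L)
  expect_lt(mean(unclass(vm$vulnerability)), 0.1)
  # vulnerability never exceeds 0.5 where the current class is the argmax
  expect_true(all(unclass(vm$vulnerability) <= 0.5 + 1e-12))
})

test_that("single-class land cover cannot train a classifier", {
  ls <- shared$landscape
  lc <- grid_raster(matrix(1L, nrow(ls$landcover), ncol(ls$landcover)),
                    cellsize = ls$cellsize)
  expect_error(fit_vulnerability(ls, landcover = lc, seed = 1L),
               "single class")
})

test_that("identity dynamics leave the unprotected step unchanged", {
  set.seed(20)
  lc <- matrix(sample(1:2, 100, TRUE), 10, 10)
  st <- make_state(lc)
  vm <- make_vm(matrix(runif(100), 10, 10), matrix(2L, 10, 10))
  tm <- make_tm(diag(2), c("forest", "degraded"))
  st2 <- step_unprotected(st, tm, vm)
  expect_identical(unclass(st2$landcover), unclass(st$landcover))
})

test_that("unprotected change takes exactly the most vulnerable cells", {
  set.seed(21)
  lc <- matrix(2L, 10, 10)
  forest_cells <- sample(100, 50)
  lc[forest_cells] <- 1L
  vul <- matrix(runif(100), 10, 10)
  st <- make_state(lc)
  vm <- make_vm(vul, matrix(2L, 10, 10))
  ann <- rbind(c(0.9, 0.1), c(0, 1))
  dimnames(ann) <- list(c("forest", "degraded"), c("forest", "degraded"))
  st2 <- step_unprotected(st, make_tm(ann, c("forest", "degraded")), vm)
  changed <- which(unclass(st2$landcover) != lc)
  expect_length(changed, 5L)
  oracle <- forest_cells[order(-vul[forest_cells])][1:5]
  expect_setequal(changed, sort(oracle))
  # conservation of the class-count vector total
  expect_equal(sum(table(unclass(st2$landcover))), 100)
})

test_that("reserves under complete SFM never change", {
  lc <- matrix(1L, 8, 8)
  rid <- matrix(1L, 8, 8)
  st <- make_state(lc, reserve_id = rid, sfm = matrix(1L, 8, 8))
  vm <- make_vm(matrix(runif(64), 8, 8), matrix(2L, 8, 8))
  for (i in 1:30) st <- step_reserves(st, quota = 10, vm)
  expect_true(all(unclass(st$landcover) == 1L))
})

test_that("the harvest quota works through reserves in vulnerability order", {
  lc <- matrix(1L, 10, 10)
  rid <- matrix(0L, 10, 10)
  rid[1:5, 1:5] <- 1L          # 25 cells, most vulnerable
  rid[6:10, 1:5] <- 2L         # next reserve
  vul <- matrix(0.1, 10, 10)
  vul[1:5, 1:5] <- 0.9
  vul[6:10, 1:5] <- 0.5
  st <- make_state(lc, reserve_id = rid)
  vm <- make_vm(vul, matrix(2L, 10, 10))
  st1 <- step_reserves(st, quota = 10, vm)
  st2 <- step_reserves(st1, quota = 10, vm)
  lc2 <- unclass(st2$landcover)
  expect_equal(sum(lc2[rid == 1] == 1L), 5L)   # 25 - 2*10
  expect_true(all(lc2[rid == 2] == 1L))        # untouched so far
  st3 <- step_reserves(st2, quota = 10, vm)
  lc3 <- unclass(st3$landcover)
  expect_equal(sum(lc3[rid == 1] == 1L), 0L)
  expect_equal(sum(lc3[rid == 2] == 1L), 20L)  # lost 5
})

test_that("a harvested reserve cell regenerates exactly 60 years later", {
  lc <- matrix(1L, 4, 4)
  rid <- matrix(1L, 4, 4)
  vul <- matrix(seq(0.9, 0.1, length.out = 16), 4, 4)
  st <- make_state(lc, reserve_id = rid)
  vm <- make_vm(vul, matrix(2L, 4, 4))
  st <- step_reserves(st, quota = 1, vm)       # year t: one cell degraded
  cell <- which(unclass(st$landcover) == 2L)
  expect_length(cell, 1L)
  for (i in 1:59) {
    st <- step_reserves(st, quota = 0, vm)
    expect_equal(unclass(st$landcover)[cell], 2L)
  }
  st <- step_reserves(st, quota = 0, vm)       # year t + 60
  expect_equal(unclass(st$landcover)[cell], 1L)
})

test_that("the simulated series conserves cells and keeps forest non-increasing", {
  ls <- shared$landscape
  st <- land_state(ls, year = 2010L)
  tm <- make_tm(ls$config$transition_truth, ls$classes)
  vm <- fit_vulnerability(ls, seed = 23L)
  run <- run_landcover(st, tm, vm, end_year = 2060L, keep_states = TRUE)
  counts <- as.matrix(run$ledger[, ls$classes])
  expect_true(all(rowSums(counts) == length(ls$landcover)))
  # unprotected forest cannot regrow under a permanence transition matrix
  strict <- unclass(ls$strict_mask) > 0
  res <- unclass(ls$reserve_id) > 0
  f0 <- sum(unclass(run$states[[1]])[!res & !strict] ==
              match("forest", ls$classes))
  fT <- sum(unclass(run$final_state$landcover)[!res & !strict] ==
              match("forest", ls$classes))
  expect_lte(fT, f0)
  # degraded reserve cells are bounded by the regeneration pipeline
  expect_lte(max(vapply(run$states, function(s)
    sum(unclass(s)[res] == match("degraded", ls$classes)), numeric(1))),
    60 * run$quota + sum(unclass(run$states[[1]])[res] ==
                           match("degraded", ls$classes)))
})

test_that("complete SFM dominates current SFM in forest at every year", {
  ls <- shared$landscape
  tm <- make_tm(ls$config$transition_truth, ls$classes)
  vm <- fit_vulnerability(ls, seed = 24L)
  run_cur <- run_landcover(apply_sfm_policy(land_state(ls), "current"),
                           tm, vm, end_year = 2050L, keep_states = FALSE)
  run_all <- run_landcover(apply_sfm_policy(land_state(ls), "all"),
                           tm, vm, end_year = 2050L, keep_states = FALSE)
  expect_true(all(run_all$ledger$forest >= run_cur$ledger$forest))
})
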