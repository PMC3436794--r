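test_that("deviance formulas match direct per-observation evaluation", {
  expect_equal(poisson_deviance(2, 1), 2 * (2 * log(2) - 1),
               tolerance = 1e-12)
  expect_equal(poisson_deviance(0, 1), 2.0, tolerance = 1e-12)
  set.seed(1)
  y <- rpois(50, 3) + runif(50)          # real-valued means of repeats
  mu <- rgamma(50, 2, 0.5) + 0.1
  oracle <- mean(vapply(seq_along(y), function(i) {
    yl <- if (y[i] > 0) y[i] * log(y[i] / mu[i]) else 0
    2 * (yl - (y[i] - mu[i]))
  }, numeric(1)))
  expect_equal(poisson_deviance(y, mu), oracle, tolerance = 1e-12)

  yb <- rbinom(50, 1, 0.5)
  p <- runif(50, 0.05, 0.95)
  oracle_b <- mean(vapply(seq_along(yb), function(i) {
    -2 * (yb[i] * log(p[i]) + (1 - yb[i]) * log(1 - p[i]))
  }, numeric(1)))
  expect_equal(binomial_deviance(yb, p), oracle_b, tolerance = 1e-12)
  # perfect probabilistic fit: deviance tends to zero
  expect_lt(binomial_deviance(yb, ifelse(yb == 1, 1 - 1e-9, 1e-9)), 1e-6)
})

test_that("MaxSSS threshold matches the exhaustive scan", {
  expect_equal(max_sss_threshold(c(0.2, 0.3, 0.7, 0.9), c(0, 0, 1, 1)),
               0.7)
  # perfectly inverted predictions: best achievable sum is 1, at a boundary
  p_inv <- c(0.9, 0.7, 0.3, 0.2); y_inv <- c(0, 0, 1, 1)
  t_inv <- max_sss_threshold(p_inv, y_inv)
  pred <- p_inv >= t_inv
  expect_equal(sum(pred & y_inv == 1) / 2 + sum(!pred & y_inv == 0) / 2, 1)
  set.seed(2)
  for (i in 1:20) {
    p <- runif(50)
    y <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_identical(max_sss_threshold(p, y), sss_brute(p, y))
  }
  expect_error(max_sss_threshold(runif(5), rep(1, 5)), "both classes")
})

test_that("confusion-matrix Kappa and rank AUC behave as known cases", {
  pred <- c(rep(TRUE, 40), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 40))
  y <- c(rep(1, 50), rep(0, 50))
  expect_equal(orangsim:::cohen_kappa(pred, y), 0.6, tolerance = 1e-12)
  set.seed(3)
  p <- runif(1000)
  yy <- rbinom(1000, 1, 0.5)
  expect_lt(abs(orangsim:::auc_rank(p, yy) - 0.5), 0.05)
  expect_equal(orangsim:::auc_rank(yy + runif(1000, 0, 0.1), yy), 1.0)
})

test_that("tree-count selection is the argmin of the D_cv curve and is deterministic", {
  set.seed(4)
  n <- 300
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rbinom(n, 1, plogis(1.5 * x[, 1] - x[, 2]))
  grid <- seq(10L, 400L, 25L)
  c1 <- fit_component(x, y, "binomial", lr = 0.05, nt_grid = grid,
                      cv_folds = 5L, seed = 9L)
  expect_equal(c1$nt, grid[which.min(c1$D_cv)])
  expect_equal(c1$D_cv_min, min(c1$D_cv))
  c2 <- fit_component(x, y, "binomial", lr = 0.05, nt_grid = grid,
                      cv_folds = 5L, seed = 9L)
  expect_identical(c1$nt, c2$nt)
  expect_equal(c1$D_cv, c2$D_cv, tolerance = 1e-12)
  # out-of-sample gain over the intercept-only model on signal data
  expect_lt(c1$D_cv_min, binomial_deviance(y, rep(mean(y), n)))
})

test_that("pure-noise responses select few trees", {
  set.seed(5)
  n <- 300
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rbinom(n, 1, 0.5)
  grid <- seq(10L, 400L, 25L)
  cmp <- fit_component(x, y, "binomial", lr = 0.05, nt_grid = grid,
                       cv_folds = 5L, seed = 10L)
  expect_lte(cmp$nt, grid[ceiling(length(grid) / 10)])
})

test_that("a degenerate one-point search equals a direct component fit", {
  cfg1 <- hurdle_fit_config(lr_grid = 0.05, tc_grid = 2L, nt_max = 300L,
                            cv_folds = 5L, seed = 7L)
  m <- optimize_hurdle(shared$gridded, cfg1)
  d <- orangsim:::dataset_xy(shared$gridded)
  direct <- fit_component(d$x, d$presence, "binomial", lr = 0.05, tc = 2L,
                          bf = 0.7, nt_grid = cfg1$nt_grid, cv_folds = 5L,
                          seed = 7L)
  expect_identical(m$binomial$nt, direct$nt)
  expect_equal(m$binomial$D_cv_min, direct$D_cv_min, tolerance = 1e-12)
  # argmin contract over the whole search table
  expect_true(all(m$search$D_cv[m$search$family == "binomial"] >=
                    m$binomial$D_cv_min - 1e-12))
  expect_true(all(m$search$D_cv[m$search$family == "poisson"] >=
                    m$poisson$D_cv_min - 1e-12))
})

test_that("a strong pairwise interaction pushes the winning tree depth past 1", {
  set.seed(6)
  n <- 500
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("v", 1:3)))
  y <- rbinom(n, 1, plogis(2.5 * x[, 1] * x[, 2]))
  ds <- make_dataset(x, y, ifelse(y == 1, rpois(n, exp(1 + x[, 1] *
                                                         x[, 2])), 0))
  cfg <- hurdle_fit_config(lr_grid = 0.05, tc_grid = c(1L, 2L),
                           nt_max = 400L, cv_folds = 5L, seed = 8L)
  m <- optimize_hurdle(ds, cfg)
  expect_gte(m$binomial$tc, 2L)
})

test_that("simplification drops a pure-noise predictor first and stops per the SE rule", {
  set.seed(7)
  n <- 400
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("s1", "s2", "s3", "noise")))
  eta <- 1.5 * x[, 1] - 1.5 * x[, 2] + 1.2 * x[, 3]
  y <- rbinom(n, 1, plogis(eta))
  cnt <- ifelse(y == 1, rpois(n, exp(0.7 + 0.6 * x[, 1] + 0.6 * x[, 2])),
                0)
  ds <- make_dataset(x, y, cnt)
  cfg <- fast_fit_config(seed = 11L)
  m <- optimize_hurdle(ds, cfg)
  s <- simplify_hurdle(m, ds, cfg)
  dropped <- union(s$simplification$dropped_binomial,
                   s$simplification$dropped_poisson)
  if (length(s$simplification$dropped_binomial) > 0)
    expect_equal(s$simplification$dropped_binomial[1], "noise")
  expect_false("s1" %in% s$simplification$dropped_binomial)
  # rule boundary: with infinite SE the loop runs to a single predictor
  comp <- m$binomial
  comp$SE_at_min <- Inf
  forced <- orangsim:::simplify_component(comp, x, y, cfg)
  expect_length(forced$component$feature_names, 1L)
  expect_length(forced$dropped, 3L)
})

test_that("hurdle composition is exactly zero below threshold, positive above", {
  d <- orangsim:::dataset_xy(shared$gridded)
  pred <- predict_hurdle(shared$model, newdata = d$x)
  p <- predict(shared$model$binomial, d$x)
  below <- p < shared$model$presence_threshold
  expect_true(all(pred[below] == 0))
  expect_true(all(pred[!below] > 0))
  # threshold 0 reduces to the Poisson part; impossible threshold zeroes all
  mu <- predict(shared$model$poisson, d$x)
  expect_equal(predict_hurdle(shared$model, newdata = d$x, threshold = 0),
               mu)
  expect_true(all(predict_hurdle(shared$model, newdata = d$x,
                                 threshold = 1.01) == 0))
})

test_that("prediction demands every retained predictor by name", {
  d <- orangsim:::dataset_xy(shared$gridded)
  x_missing <- d$x[, setdiff(colnames(d$x), "elevation")]
  expect_error(predict_hurdle(shared$model, newdata = x_missing),
               "elevation")
})

test_that("model evaluation metrics are coherent on the shared fit", {
  met <- evaluate_hurdle(shared$model, shared$gridded)
  expect_gte(met$auc, 0.5)
  expect_lte(met$auc, 1)
  expect_true(all(met$D_resid <= met$D_null))
  expect_true(all(is.finite(unlist(met[c("auc", "kappa", "mse",
                                         "rmpe")]))))
  expect_length(met$kappa_threshold_components, 5L)
  expect_equal(met$kappa_threshold,
               mean(met$kappa_threshold_components))
})

test_that("validation regression recovers exact and contaminated fits", {
  x <- seq(0.5, 10, by = 0.5)
  v <- cross_dataset_validation(x, x)
  expect_equal(unname(v$ols), c(0, 1), tolerance = 1e-10)
  expect_equal(unname(v$robust), c(0, 1), tolerance = 1e-6)
  # closed-form normal equations oracle
  set.seed(12)
  y2 <- 2 * x + 1 + rnorm(length(x), 0, 0.3)
  v2 <- cross_dataset_validation(x, y2)
  xm <- cbind(1, x)
  beta <- solve(t(xm) %*% xm, t(xm) %*% y2)
  expect_equal(unname(v2$ols), as.vector(beta), tolerance = 1e-10)
  # a gross outlier pulls OLS but not the Huber fit
  y3 <- 2 * x + 1
  y3[3] <- 60
  v3 <- cross_dataset_validation(x, y3)
  expect_lt(abs(v3$robust["slope"] - 2), abs(v3$ols["slope"] - 2))
  expect_error(cross_dataset_validation(rep(1, 5), 1:5), "variance")
})
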