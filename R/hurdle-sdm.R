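#' Mean binomial and Poisson deviance
#'
#' Per-observation predictive deviances used for cross-validated tree-count
#' selection and for reporting null/residual deviance. Binomial:
#' mean of \eqn{-2[y \log p + (1-y) \log(1-p)]}. Poisson:
#' mean of \eqn{2[y \log(y/\mu) - (y - \mu)]} with the convention
#' \eqn{y \log(y/\mu) = 0} at \eqn{y = 0}. Averaged counts are real-valued,
#' so `y` need not be integer in the Poisson form (quasi-likelihood
#' reading). Probabilities are clamped to `[eps, 1 - eps]` before taking
#' logs.
#'
#' @param y response vector (0/1 for binomial; non-negative reals for
#'   Poisson).
#' @param p,mu predictions (probabilities; positive means).
#' @param eps clamping epsilon for probabilities.
#' @return mean deviance (scalar).
#' @export
binomial_deviance <- function(y, p, eps = 1e-12) {
  stopifnot(length(y) == length(p))
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' @rdname binomial_deviance
#' @export
poisson_deviance <- function(y, mu) {
  stopifnot(length(y) == length(mu), all(y >= 0), all(mu > 0))
  ylogy <- ifelse(y > 0, y * log(y / mu), 0)
  mean(2 * (ylogy - (y - mu)))
}

#' Fitting configuration for the hurdle boosted-tree model
#'
#' The default search space follows standard practice for boosted
#' regression trees in species distribution modelling: learning rates
#' `{0.01, 0.005, 0.001}`, tree complexities (interaction depths) `{1, 2,
#' 3}`, bag fraction 0.7, tree counts on a grid from 10 upward in steps of
#' 25, and 10-fold cross-validation for tree-count selection. `nt_max`
#' defaults to 1500 here, a desk-scale cap; set 15000 to search the full
#' classical grid.
#'
#' @param lr_grid learning rates to search.
#' @param tc_grid interaction depths to search.
#' @param bf bag fraction in (0, 1].
#' @param nt_min,nt_max,nt_step tree-count grid `seq(nt_min, nt_max,
#'   nt_step)`.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed controlling fold assignment and boosting
#'   subsampling.
#' @return object of class `hurdle_fit_config`.
#' @export
hurdle_fit_config <- function(lr_grid = c(0.01, 0.005, 0.001),
                              tc_grid = c(1L, 2L, 3L), bf = 0.7,
                              nt_min = 10L, nt_max = 1500L, nt_step = 25L,
                              cv_folds = 10L, seed = 1L) {
  stopifnot(length(lr_grid) >= 1, all(lr_grid > 0),
            length(tc_grid) >= 1, all(tc_grid >= 1),
            bf > 0, bf <= 1, nt_min >= 1, nt_max >= nt_min, nt_step >= 1,
            cv_folds >= 2)
  structure(list(lr_grid = lr_grid, tc_grid = as.integer(tc_grid), bf = bf,
                 nt_grid = seq(as.integer(nt_min), as.integer(nt_max),
                               by = as.integer(nt_step)),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "hurdle_fit_config")
}

make_folds <- function(y, k, stratify, seed) {
  set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cls in unique(y > 0)) {
      idx <- which((y > 0) == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

xgb_params <- function(family, lr, tc, bf, seed) {
  list(objective = if (family == "binomial") "binary:logistic"
       else "count:poisson",
       eta = lr, max_depth = tc, subsample = bf, nthread = 1,
       seed = seed)
}

deviance_fun <- function(family) {
  if (family == "binomial") binomial_deviance else poisson_deviance
}

#' Fit one boosted-tree hurdle component with cross-validated tree count
#'
#' Fits a stagewise gradient-boosted tree ensemble (binomial or Poisson
#' loss) and selects the number of trees `nt` on a grid by minimizing the
#' mean held-out predictive deviance over cross-validation folds
#' (\eqn{D_{cv}}). For each fold a single staged fit at the maximum grid
#' value is evaluated on the held-out fold at every grid value, giving the
#' full \eqn{D_{cv}(nt)} curve and its fold-to-fold standard error; the
#' component is then refit on all data at the argmin. Fold assignment is
#' stratified by presence for the binomial family.
#'
#' @param x numeric predictor matrix (rows = cells).
#' @param y response (0/1 or non-negative mean counts).
#' @param family `"binomial"` or `"poisson"`.
#' @param lr,tc,bf learning rate, interaction depth, bag fraction.
#' @param nt_grid increasing integer grid of candidate tree counts.
#' @param cv_folds number of folds (must not exceed `nrow(x)`).
#' @param seed integer seed (fold assignment and subsampling).
#' @return object of class `brt_component`: the fitted booster plus the
#'   selected `nt`, the `D_cv` curve, `SE_Dcv` at every grid point,
#'   `D_cv_min`, `SE_at_min`, null/residual training deviance and
#'   per-predictor relative influence (per cent).
#' @export
fit_component <- function(x, y, family = c("binomial", "poisson"),
                          lr = 0.01, tc = 2L, bf = 0.7,
                          nt_grid = seq(10L, 1500L, 25L), cv_folds = 10L,
                          seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(diff(nt_grid) > 0))
  if (nrow(x) < cv_folds)
    stop(sprintf("fewer rows (%d) than folds (%d)", nrow(x), cv_folds),
         call. = FALSE)
  if (family == "binomial" && length(unique(y)) < 2)
    stop("binomial component needs both classes present", call. = FALSE)
  dev_fn <- deviance_fun(family)
  nt_max <- max(nt_grid)
  fold <- make_folds(y, cv_folds, stratify = family == "binomial",
                     seed = seed)
  dev <- matrix(NA_real_, cv_folds, length(nt_grid))
  for (k in seq_len(cv_folds)) {
    tr <- fold != k; te <- !tr
    bst <- xgboost::xgb.train(
      params = xgb_params(family, lr, tc, bf, seed + k),
      data = xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr]),
      nrounds = nt_max, verbose = 0)
    xte <- x[te, , drop = FALSE]
    for (j in seq_along(nt_grid)) {
      pr <- predict(bst, xte, iterationrange = c(1L, nt_grid[j]))
      dev[k, j] <- dev_fn(y[te], if (family == "binomial") pr
                          else pmax(pr, 1e-12))
    }
  }
  d_cv <- colMeans(dev)
  se_cv <- apply(dev, 2, stats::sd) / sqrt(cv_folds)
  best <- which.min(d_cv)
  nt <- nt_grid[best]
  booster <- xgboost::xgb.train(
    params = xgb_params(family, lr, tc, bf, seed),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = nt, verbose = 0)
  fitted <- predict(booster, x)
  if (family == "poisson") fitted <- pmax(fitted, 1e-12)
  d_null <- if (family == "binomial")
    binomial_deviance(y, rep(mean(y), length(y)))
  else poisson_deviance(y, rep(max(mean(y), 1e-12), length(y)))
  d_resid <- dev_fn(y, fitted)
  structure(list(booster = booster, family = family, lr = lr, tc = tc,
                 bf = bf, nt = nt, nt_grid = nt_grid, D_cv = d_cv,
                 SE_Dcv = se_cv, D_cv_min = d_cv[best],
                 SE_at_min = se_cv[best], D_null = d_null,
                 D_resid = d_resid, seed = seed,
                 feature_names = colnames(x),
                 influence = relative_influence(booster, colnames(x))),
            class = "brt_component")
}

relative_influence <- function(booster, feature_names) {
  imp <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  out <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp) > 0)
    out[imp$Feature] <- imp$Gain * 100
  out
}

#' Predict from one hurdle component
#'
#' @param object a `brt_component`.
#' @param newdata matrix or data.frame containing at least the component's
#'   training predictors.
#' @param ... unused.
#' @return probabilities (binomial) or expected counts (Poisson).
#' @export
predict.brt_component <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, object$feature_names,
                                         drop = FALSE])
  p <- predict(object$booster, nd)
  if (object$family == "poisson") p <- pmax(p, 0)
  p
}

dataset_xy <- function(data, predictors = NULL) {
  if (is.null(predictors)) predictors <- attr(data, "predictors")
  if (is.null(predictors))
    stop("dataset carries no predictor column attribute", call. = FALSE)
  list(x = as.matrix(as.data.frame(data)[, predictors, drop = FALSE]),
       presence = data$presence, count = data$mean_count)
}

#' Optimize the two-part hurdle model over the fitting-parameter grid
#'
#' Fits the binomial (presence/absence over all cells, pseudoabsences
#' included) and Poisson (mean count on presence cells only, "abundance
#' contingent on presence") components separately at every learning-rate x
#' tree-complexity combination, each with cross-validated tree-count
#' selection, and keeps per component the combination minimizing
#' \eqn{D_{cv}}. The presence threshold stored on the model is the maximum
#' sensitivity-plus-specificity (MaxSSS) threshold of the binomial training
#' predictions, the rule that down-weights the influence of pseudoabsences.
#'
#' @param data a `gridded_dataset` from [aggregate_counts()].
#' @param config a [hurdle_fit_config()].
#' @param quiet suppress per-combination progress messages.
#' @return object of class `hurdle_model` with elements `binomial`,
#'   `poisson` (both `brt_component`), `presence_threshold`, `predictors`,
#'   `search` (grid bookkeeping) and `config`.
#' @export
optimize_hurdle <- function(data, config = hurdle_fit_config(),
                            quiet = TRUE) {
  stopifnot(inherits(config, "hurdle_fit_config"))
  d <- dataset_xy(data)
  pres_idx <- which(d$presence == 1)
  grid <- expand.grid(lr = config$lr_grid, tc = config$tc_grid)
  fit_best <- function(x, y, family) {
    best <- NULL; rows <- list()
    for (g in seq_len(nrow(grid))) {
      cmp <- fit_component(x, y, family, lr = grid$lr[g], tc = grid$tc[g],
                           bf = config$bf, nt_grid = config$nt_grid,
                           cv_folds = config$cv_folds, seed = config$seed)
      rows[[g]] <- data.frame(family = family, lr = grid$lr[g],
                              tc = grid$tc[g], nt = cmp$nt,
                              D_cv = cmp$D_cv_min, SE_Dcv = cmp$SE_at_min)
      if (!quiet)
        message(sprintf("%s lr=%g tc=%d -> nt=%d Dcv=%.4f", family,
                        grid$lr[g], grid$tc[g], cmp$nt, cmp$D_cv_min))
      if (is.null(best) || cmp$D_cv_min < best$D_cv_min) best <- cmp
    }
    list(component = best, table = do.call(rbind, rows))
  }
  bin <- fit_best(d$x, d$presence, "binomial")
  poi <- fit_best(d$x[pres_idx, , drop = FALSE], d$count[pres_idx],
                  "poisson")
  p_train <- predict(bin$component, d$x)
  thr <- max_sss_threshold(p_train, d$presence)
  structure(list(binomial = bin$component, poisson = poi$component,
                 presence_threshold = thr,
                 predictors = colnames(d$x),
                 search = rbind(bin$table, poi$table), config = config),
            class = "hurdle_model")
}

simplify_component <- function(component, x, y, config) {
  d0 <- component$D_cv_min
  se0 <- component$SE_at_min
  current <- component
  dropped <- character()
  while (length(current$feature_names) > 1) {
    infl <- current$influence
    drop_var <- names(infl)[order(infl, seq_along(infl))][1]
    keep <- setdiff(current$feature_names, drop_var)
    cand <- fit_component(x[, keep, drop = FALSE], y, component$family,
                          lr = component$lr, tc = component$tc,
                          bf = component$bf, nt_grid = config$nt_grid,
                          cv_folds = config$cv_folds, seed = config$seed)
    if (cand$D_cv_min - d0 > se0) break
    current <- cand
    dropped <- c(dropped, drop_var)
  }
  list(component = current, dropped = dropped)
}

#' Simplify the hurdle model by backward predictor elimination
#'
#' Iteratively removes the predictor with the lowest relative influence and
#' refits, stopping when the increase in \eqn{D_{cv}} over the saturated
#' model exceeds the saturated model's cross-validation deviance standard
#' error. The rule is applied to the binomial part, the Poisson part, and
#' both together; the returned model is the variant with the lowest summed
#' component \eqn{D_{cv}} (so a saturated model that cannot be simplified
#' without loss is retained).
#'
#' @param model a fitted `hurdle_model`.
#' @param data the `gridded_dataset` the model was fit on.
#' @param config a [hurdle_fit_config()] (tree grid, folds, seed for the
#'   refits).
#' @return the selected `hurdle_model`, with a `simplification` element
#'   recording each variant's component \eqn{D_{cv}} and dropped
#'   predictors.
#' @export
simplify_hurdle <- function(model, data, config = model$config) {
  d <- dataset_xy(data, model$predictors)
  pres_idx <- which(d$presence == 1)
  sb <- simplify_component(model$binomial, d$x, d$presence, config)
  sp <- simplify_component(model$poisson,
                           d$x[pres_idx, , drop = FALSE],
                           d$count[pres_idx], config)
  variants <- list(
    saturated = list(bin = model$binomial, poi = model$poisson,
                     dropped_bin = character(),
                     dropped_poi = character()),
    binomial = list(bin = sb$component, poi = model$poisson,
                    dropped_bin = sb$dropped, dropped_poi = character()),
    poisson = list(bin = model$binomial, poi = sp$component,
                   dropped_bin = character(), dropped_poi = sp$dropped),
    binomial_and_poisson = list(bin = sb$component, poi = sp$component,
                                dropped_bin = sb$dropped,
                                dropped_poi = sp$dropped))
  tab <- do.call(rbind, lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    data.frame(variant = nm, D_cv_binomial = v$bin$D_cv_min,
               SE_binomial = v$bin$SE_at_min,
               D_cv_poisson = v$poi$D_cv_min,
               SE_poisson = v$poi$SE_at_min,
               n_dropped = length(v$dropped_bin) + length(v$dropped_poi))
  }))
  tab$D_cv_total <- tab$D_cv_binomial + tab$D_cv_poisson
  pick <- tab$variant[which.min(tab$D_cv_total)]
  v <- variants[[pick]]
  out <- model
  out$binomial <- v$bin
  out$poisson <- v$poi
  p_train <- predict(v$bin, d$x)
  out$presence_threshold <- max_sss_threshold(p_train, d$presence)
  out$simplification <- list(table = tab, selected = pick,
                             dropped_binomial = v$dropped_bin,
                             dropped_poisson = v$dropped_poi)
  out
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans every unique predicted probability as a candidate cut-off
#' (prediction >= threshold means presence) and returns the one maximizing
#' sensitivity + specificity; exact ties are broken in favour of the
#' smallest threshold.
#'
#' @param p predicted probabilities.
#' @param y observed 0/1 presence.
#' @return threshold (scalar).
#' @export
max_sss_threshold <- function(p, y) {
  stopifnot(length(p) == length(y))
  if (length(unique(y)) < 2)
    stop("both classes must be present to choose a threshold",
         call. = FALSE)
  cand <- sort(unique(p))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  best_t <- cand[1]; best_s <- -Inf
  for (t in cand) {
    pred <- p >= t
    s <- sum(pred & y == 1) / n_pos + sum(!pred & y == 0) / n_neg
    if (s > best_s + 1e-12) {
      best_s <- s; best_t <- t
    }
  }
  best_t
}

auc_rank <- function(p, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

cohen_kappa <- function(pred, y) {
  n <- length(y)
  tp <- sum(pred & y == 1); tn <- sum(!pred & y == 0)
  fp <- sum(pred & y == 0); fn <- sum(!pred & y == 1)
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

max_kappa_threshold <- function(p, y) {
  cand <- sort(unique(p))
  ks <- vapply(cand, function(t) cohen_kappa(p >= t, y), numeric(1))
  cand[which.max(ks)]
}

#' Evaluate a fitted hurdle model
#'
#' Binomial part: AUC (rank statistic) and Cohen's Kappa at the mean of
#' five standard thresholding rules (fixed 0.5, observed prevalence, mean
#' predicted probability, max-Kappa, MaxSSS). Poisson part: mean squared
#' error and relative mean prediction error (mean absolute error divided by
#' the mean observed count) on presence cells. Deviance explained
#' \eqn{1 - D_{resid}/D_{null}} is reported per component and pooled over
#' both components by summing numerators and denominators.
#'
#' @param model a fitted `hurdle_model`.
#' @param data a `gridded_dataset`.
#' @return object of class `hurdle_metrics` (a list).
#' @export
evaluate_hurdle <- function(model, data) {
  d <- dataset_xy(data, model$predictors)
  p <- predict(model$binomial, d$x)
  pres_idx <- which(d$presence == 1)
  mu <- predict(model$poisson, d$x[pres_idx, , drop = FALSE])
  thr5 <- c(0.5, mean(d$presence), mean(p), max_kappa_threshold(p,
                                                                d$presence),
            max_sss_threshold(p, d$presence))
  thr <- mean(thr5)
  y_cnt <- d$count[pres_idx]
  err <- mu - y_cnt
  dn_b <- model$binomial$D_null; dr_b <- model$binomial$D_resid
  dn_p <- model$poisson$D_null; dr_p <- model$poisson$D_resid
  # overall rmpe over all cells using the composed hurdle prediction
  hurdle_pred <- predict_hurdle(model, newdata = d$x)
  structure(list(
    auc = auc_rank(p, d$presence),
    kappa = cohen_kappa(p >= thr, d$presence),
    kappa_threshold = thr, kappa_threshold_components = thr5,
    mse = mean(err^2),
    rmpe = mean(abs(err)) / mean(y_cnt),
    rmpe_overall = mean(abs(hurdle_pred - d$count)) /
      max(mean(d$count), 1e-12),
    D_cv = c(binomial = model$binomial$D_cv_min,
             poisson = model$poisson$D_cv_min),
    SE_Dcv = c(binomial = model$binomial$SE_at_min,
               poisson = model$poisson$SE_at_min),
    D_null = c(binomial = dn_b, poisson = dn_p),
    D_resid = c(binomial = dr_b, poisson = dr_p),
    deviance_explained = c(binomial = 1 - dr_b / dn_b,
                           poisson = 1 - dr_p / dn_p,
                           pooled = 1 - (dr_b + dr_p) / (dn_b + dn_p))),
    class = "hurdle_metrics")
}

#' Predict expected nest counts from the hurdle model
#'
#' Composes the two parts: the Poisson-part expected count where the
#' binomial-part presence probability reaches the model's presence
#' threshold, zero elsewhere.
#'
#' @param model a fitted `hurdle_model`.
#' @param landscape optional `landscape`; predictions are returned as a
#'   `grid_raster` over its grid.
#' @param newdata alternatively, a matrix/data.frame of predictors.
#' @param overrides optional layer overrides passed to
#'   [predictor_matrix()] (dynamic land cover, projected climate).
#' @param threshold presence threshold; defaults to the fitted MaxSSS
#'   value.
#' @return `grid_raster` (landscape input) or numeric vector (matrix
#'   input).
#' @export
predict_hurdle <- function(model, landscape = NULL, newdata = NULL,
                           overrides = NULL,
                           threshold = model$presence_threshold) {
  if (is.null(newdata)) {
    stopifnot(inherits(landscape, "landscape"))
    newdata <- predictor_matrix(landscape, overrides)
  }
  nd <- as.data.frame(newdata)
  miss <- setdiff(model$predictors, colnames(nd))
  if (length(miss))
    stop(sprintf("missing predictor(s) for prediction: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  p <- predict(model$binomial, nd)
  mu <- predict(model$poisson, nd)
  out <- ifelse(p >= threshold, mu, 0)
  if (!is.null(landscape) && inherits(landscape, "landscape")) {
    dims <- dim(landscape$landcover)
    return(grid_raster(matrix(out, dims[1], dims[2]),
                       cellsize = landscape$cellsize))
  }
  out
}

#' Validate predictions against an independent count dataset
#'
#' Regresses independent observed counts on model predictions with ordinary
#' least squares and with a robust linear fit (Huber weights, iterated
#' re-weighted least squares).
#'
#' @param predictions model-predicted counts.
#' @param independent_counts paired independent observations.
#' @return list with `ols` and `robust`, each `c(intercept, slope)`, plus
#'   the underlying fit objects.
#' @export
cross_dataset_validation <- function(predictions, independent_counts) {
  stopifnot(length(predictions) == length(independent_counts))
  if (length(predictions) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(predictions) == 0)
    stop("predictions have zero variance", call. = FALSE)
  df <- data.frame(x = predictions, y = independent_counts)
  ols <- stats::lm(y ~ x, data = df)
  rob <- MASS::rlm(y ~ x, data = df, psi = MASS::psi.huber, maxit = 100)
  list(ols = stats::setNames(stats::coef(ols), c("intercept", "slope")),
       robust = stats::setNames(stats::coef(rob), c("intercept", "slope")),
       ols_fit = ols, robust_fit = rob)
}
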