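#' Estimate the annual land-cover transition matrix from two epochs
#'
#' Cross-tabulates class transitions between two observed land-cover
#' rasters (optionally restricted by a mask, e.g. excluding strictly
#' protected areas where no extraction occurs), row-normalizes to the
#' interval transition matrix, and annualizes it by the matrix
#' `1/interval_years` root computed via eigendecomposition; any small
#' negative entries produced by the root are clipped to zero and rows
#' renormalized. Classes absent at the first epoch receive an identity row
#' with a warning.
#'
#' @param lc_t0,lc_t1 aligned `grid_raster`s of class codes
#'   (1..K).
#' @param classes character vector of class labels in code order.
#' @param interval_years years separating the two epochs.
#' @param mask optional logical matrix/`grid_raster`; only `TRUE` cells
#'   enter the estimation.
#' @return object of class `transition_model`: `annual_matrix`,
#'   `interval_matrix`, `interval_years`, `classes`, `counts`.
#' @export
estimate_transition <- function(lc_t0, lc_t1, classes,
                                interval_years = 10L, mask = NULL) {
  stop_if_misaligned(lc_t0, lc_t1, "land-cover rasters")
  a <- raster_values(lc_t0); b <- raster_values(lc_t1)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "grid_raster")) raster_values(mask) > 0
    else mask > 0
    stop_if_misaligned(lc_t0, m, "land-cover raster and mask")
    a <- a[m]; b <- b[m]
  }
  k <- length(classes)
  counts <- matrix(0, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k)) for (j in seq_len(k))
    counts[i, j] <- sum(a == i & b == j)
  interval <- counts
  for (i in seq_len(k)) {
    rs <- sum(counts[i, ])
    if (rs == 0) {
      warning(sprintf(
        "class '%s' absent at t0; using an identity transition row",
        classes[i]), call. = FALSE)
      interval[i, ] <- 0; interval[i, i] <- 1
    } else {
      interval[i, ] <- counts[i, ] / rs
    }
  }
  annual <- matrix_root(interval, interval_years)
  check_row_stochastic(annual, tol = 1e-9, what = "annual matrix")
  check_row_stochastic(interval, tol = 1e-9, what = "interval matrix")
  structure(list(annual_matrix = annual, interval_matrix = interval,
                 interval_years = as.integer(interval_years),
                 classes = classes, counts = counts),
            class = "transition_model")
}

# n-th root of a stochastic matrix by eigendecomposition; complex parts
# from numerically conjugate eigenvalues are discarded, negatives clipped
# and rows renormalized.
matrix_root <- function(m, n) {
  e <- eigen(m)
  lam <- as.complex(e$values)^(1 / n)
  root <- Re(e$vectors %*% diag(lam, nrow = length(lam)) %*%
               solve(e$vectors))
  root[root < 0] <- 0
  root <- root / rowSums(root)
  dimnames(root) <- dimnames(m)
  root
}

#' Vulnerability and target class from class-membership probabilities
#'
#' Given per-cell class-membership probabilities, a cell's vulnerability to
#' change is the maximum probability of membership to any class other than
#' the predicted (most probable) class, and its target class is the class
#' with the second-highest probability. Ties are broken toward the earlier
#' class in the legend order.
#'
#' @param probs n x K matrix of membership probabilities (rows sum to 1).
#' @param classes class labels in column order.
#' @return list with integer vectors `predicted`, `target` and numeric
#'   `vulnerability`.
#' @export
vulnerability_from_probs <- function(probs, classes) {
  stopifnot(ncol(probs) == length(classes))
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("membership probabilities must sum to 1 per cell", call. = FALSE)
  n <- nrow(probs)
  predicted <- integer(n); target <- integer(n)
  vulnerability <- numeric(n)
  for (i in seq_len(n)) {
    pr <- probs[i, ]
    predicted[i] <- which.max(pr)          # earliest class wins ties
    pr2 <- pr; pr2[predicted[i]] <- -Inf
    target[i] <- which.max(pr2)
    vulnerability[i] <- pr[target[i]]
  }
  list(predicted = predicted, target = target,
       vulnerability = vulnerability)
}

#' Fit the land-cover vulnerability map
#'
#' Fits a random-forest classifier of current land-cover class on the
#' static spatial predictors (terrain, distances, protection status); the
#' forest's vote proportions give each cell's probability of membership to
#' each class, from which vulnerability and target class follow via
#' [vulnerability_from_probs()].
#'
#' @param landscape a `landscape`.
#' @param landcover optional `grid_raster` of class codes (defaults to the
#'   landscape's).
#' @param seed integer RNG seed.
#' @param ntree number of trees.
#' @return object of class `vulnerability_map`: `probs`, `vulnerability`
#'   and `target_class` (`grid_raster`s), `predicted_class`, `classes`.
#' @export
fit_vulnerability <- function(landscape, landcover = NULL, seed = 1L,
                              ntree = 300L) {
  stopifnot(inherits(landscape, "landscape"))
  if (is.null(landcover)) landcover <- landscape$landcover
  lc <- raster_values(landcover)
  x <- predictor_matrix(landscape)
  static <- c("popdist", "roaddist", "riverdist", "protectarea",
              "elevation", "slope", "temperature", "precip_wet",
              "precip_dry")
  x <- x[, static, drop = FALSE]
  x <- cbind(x, reserve = as.numeric(raster_values(
    landscape$reserve_id) > 0))
  y <- factor(landscape$classes[as.vector(lc)],
              levels = landscape$classes)
  if (length(unique(y)) < 2)
    stop("land cover has a single class; cannot fit a classifier",
         call. = FALSE)
  y <- droplevels(y)
  set.seed(seed)
  rf <- randomForest::randomForest(x = as.data.frame(x), y = y,
                                   ntree = ntree)
  pr <- predict(rf, as.data.frame(x), type = "prob")
  probs <- matrix(0, nrow(x), length(landscape$classes),
                  dimnames = list(NULL, landscape$classes))
  probs[, colnames(pr)] <- pr
  v <- vulnerability_from_probs(probs, landscape$classes)
  dims <- dim(lc)
  gr <- function(vals) grid_raster(matrix(vals, dims[1], dims[2]),
                                   cellsize = landscape$cellsize)
  structure(list(probs = probs, vulnerability = gr(v$vulnerability),
                 target_class = gr(v$target),
                 predicted_class = gr(v$predicted),
                 classes = landscape$classes),
            class = "vulnerability_map")
}

#' Construct a land-cover simulation state
#'
#' @param landscape a `landscape`.
#' @param year starting calendar year.
#' @return object of class `land_state`: class raster, reserve ids, SFM and
#'   strict-protection masks, per-cell regeneration clock, year.
#' @export
land_state <- function(landscape, year = 2010L) {
  structure(list(landcover = landscape$landcover,
                 reserve_id = landscape$reserve_id,
                 sfm_mask = landscape$sfm_mask,
                 strict_mask = landscape$strict_mask,
                 regen_clock = grid_raster(
                   matrix(0L, nrow(landscape$landcover),
                          ncol(landscape$landcover)),
                   cellsize = landscape$cellsize),
                 classes = landscape$classes,
                 cellsize = landscape$cellsize,
                 year = as.integer(year)),
            class = "land_state")
}

#' Set the sustainable-forest-management policy on a state
#'
#' @param state a `land_state`.
#' @param policy `"current"` keeps the landscape's current SFM reserves;
#'   `"all"` places every reserve under SFM.
#' @return the modified state.
#' @export
apply_sfm_policy <- function(state, policy = c("current", "all")) {
  policy <- match.arg(policy)
  if (policy == "all") {
    m <- raster_values(state$reserve_id) > 0
    state$sfm_mask <- grid_raster(m * 1L, cellsize = state$cellsize)
  }
  state
}

# integer apportionment: floors plus largest remainders, so that the
# destination totals sum to the rounded expected total leaving the class
apportion_movers <- function(expected) {
  total <- round(sum(expected))
  base <- floor(expected)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- expected - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' One annual step of unprotected land-cover change
#'
#' Applies the annual Markov transition matrix to unprotected cells
#' (outside reserves and strictly protected areas). For each source class
#' the expected number of movers to each destination is the annual rate
#' times the class's unprotected cell count (largest-remainder rounding);
#' the cells changed are the most vulnerable cells of that class whose
#' target class matches the destination, with any shortfall filled by the
#' next-most-vulnerable cells of the class regardless of their target.
#' Conversion is permanent in the sense that no regeneration clock is set.
#'
#' @param state a `land_state`.
#' @param tm a `transition_model`.
#' @param vm a `vulnerability_map`.
#' @return the advanced state (year unchanged; [run_landcover()] manages
#'   the calendar).
#' @export
step_unprotected <- function(state, tm, vm) {
  lc <- raster_values(state$landcover)
  unprot <- raster_values(state$reserve_id) == 0 &
    raster_values(state$strict_mask) == 0
  vul <- raster_values(vm$vulnerability)
  tgt <- raster_values(vm$target_class)
  k <- length(state$classes)
  annual <- tm$annual_matrix
  changes_idx <- integer(); changes_to <- integer()
  for (src in seq_len(k)) {
    cells <- which(lc == src & unprot)
    if (length(cells) == 0) next
    dests <- setdiff(seq_len(k), src)
    movers <- apportion_movers(annual[src, dests] * length(cells))
    if (sum(movers) == 0) next
    ord <- cells[order(-vul[cells])]
    taken <- rep(FALSE, length(ord))
    shortfall <- integer(length(dests))
    for (di in seq_along(dests)) {
      want <- movers[di]
      if (want == 0) next
      pick <- which(!taken & tgt[ord] == dests[di])[seq_len(min(want,
        sum(!taken & tgt[ord] == dests[di])))]
      taken[pick] <- TRUE
      changes_idx <- c(changes_idx, ord[pick])
      changes_to <- c(changes_to, rep(dests[di], length(pick)))
      shortfall[di] <- want - length(pick)
    }
    for (di in seq_along(dests)) {
      if (shortfall[di] == 0) next
      pick <- which(!taken)[seq_len(min(shortfall[di], sum(!taken)))]
      taken[pick] <- TRUE
      changes_idx <- c(changes_idx, ord[pick])
      changes_to <- c(changes_to, rep(dests[di], length(pick)))
    }
  }
  lc[changes_idx] <- changes_to
  state$landcover <- grid_raster(lc, cellsize = state$cellsize)
  state
}

#' One annual step of reserve harvest and regeneration
#'
#' Reserves under SFM are untouched. Other reserves are processed in
#' decreasing order of the mean vulnerability of their remaining forest
#' cells; a constant state-wide annual harvest quota (independent of
#' remaining forest) consumes the most vulnerable forest cells of the
#' current reserve before moving to the next. Harvesting a cell makes it
#' degraded and starts its regeneration clock; clocks on degraded reserve
#' cells advance one year per step and a cell reverts to forest exactly
#' `regen_years` years after it was harvested.
#'
#' @param state a `land_state`.
#' @param quota constant harvest, cells per year (state-wide).
#' @param vm a `vulnerability_map`.
#' @param regen_years years from degradation to regeneration (default 60).
#' @return the advanced state.
#' @export
step_reserves <- function(state, quota, vm, regen_years = 60L) {
  stopifnot(quota >= 0)
  lc <- raster_values(state$landcover)
  clock <- raster_values(state$regen_clock)
  res <- raster_values(state$reserve_id)
  sfm <- raster_values(state$sfm_mask) > 0
  vul <- raster_values(vm$vulnerability)
  forest_code <- match("forest", state$classes)
  degraded_code <- match("degraded", state$classes)

  # regeneration: advance clocks on degraded reserve cells, revert at term
  ticking <- res > 0 & lc == degraded_code & clock > 0
  clock[ticking] <- clock[ticking] + 1L
  done <- ticking & clock >= regen_years + 1L
  lc[done] <- forest_code
  clock[done] <- 0L

  # constant harvest over non-SFM reserves in vulnerability order
  remaining <- as.integer(round(quota))
  if (remaining > 0) {
    ids <- setdiff(sort(unique(res[res > 0])), unique(res[sfm]))
    if (length(ids)) {
      mean_vul <- vapply(ids, function(id) {
        f <- which(res == id & lc == forest_code)
        if (length(f) == 0) -Inf else mean(vul[f])
      }, numeric(1))
      for (id in ids[order(-mean_vul)]) {
        if (remaining <= 0) break
        f <- which(res == id & lc == forest_code)
        if (length(f) == 0) next
        take <- f[order(-vul[f])][seq_len(min(remaining, length(f)))]
        lc[take] <- degraded_code
        clock[take] <- 1L
        remaining <- remaining - length(take)
      }
    }
  }
  state$landcover <- grid_raster(lc, cellsize = state$cellsize)
  state$regen_clock <- grid_raster(clock, cellsize = state$cellsize)
  state
}

#' Default constant reserve-harvest quota
#'
#' The constant harvest is the reserve deforestation rate applied once to
#' the initial non-SFM reserve forest area and then held fixed
#' ("independent of remaining forest").
#'
#' @param state the initial `land_state` (after policy application).
#' @param rate annual reserve deforestation rate (proportion of forest per
#'   year).
#' @return integer cells per year.
#' @export
reserve_harvest_quota <- function(state, rate) {
  lc <- raster_values(state$landcover)
  res <- raster_values(state$reserve_id)
  sfm <- raster_values(state$sfm_mask) > 0
  forest_code <- match("forest", state$classes)
  n0 <- sum(res > 0 & !sfm & lc == forest_code)
  as.integer(round(rate * n0))
}

#' Run the land-cover simulation over a span of years
#'
#' Applies, for every year, one unprotected Markov step followed by one
#' reserve harvest/regeneration step, and records the per-year class-count
#' ledger and land-cover states.
#'
#' @param state0 initial `land_state` (its `year` is the start).
#' @param tm `transition_model` for unprotected land.
#' @param vm `vulnerability_map`.
#' @param end_year final simulated year (> start year).
#' @param quota constant reserve harvest (cells/year); defaults to
#'   [reserve_harvest_quota()] at the rate implied by the annual matrix's
#'   forest row.
#' @param regen_years regeneration delay in years.
#' @param keep_states store the class raster of every year (otherwise only
#'   first and last).
#' @return object of class `landcover_series`: `states` (named list of
#'   `grid_raster`s), `ledger` (data.frame year x class counts), `quota`,
#'   `years`.
#' @export
run_landcover <- function(state0, tm, vm, end_year, quota = NULL,
                          regen_years = 60L, keep_states = TRUE) {
  stopifnot(inherits(state0, "land_state"), end_year > state0$year)
  forest_code <- match("forest", state0$classes)
  if (is.null(quota))
    quota <- reserve_harvest_quota(
      state0, 1 - tm$annual_matrix[forest_code, forest_code])
  years <- state0$year:end_year
  k <- length(state0$classes)
  ledger <- matrix(0L, length(years), k,
                   dimnames = list(years, state0$classes))
  states <- list()
  st <- state0
  count_classes <- function(lc) {
    vapply(seq_len(k), function(cc) sum(raster_values(lc) == cc),
           integer(1))
  }
  ledger[1, ] <- count_classes(st$landcover)
  states[[as.character(years[1])]] <- st$landcover
  for (i in seq_along(years)[-1]) {
    st <- step_unprotected(st, tm, vm)
    st <- step_reserves(st, quota, vm, regen_years)
    st$year <- years[i]
    ledger[i, ] <- count_classes(st$landcover)
    if (keep_states || i == length(years))
      states[[as.character(years[i])]] <- st$landcover
  }
  structure(list(states = states,
                 ledger = data.frame(year = years, ledger,
                                     check.names = FALSE),
                 quota = quota, years = years, classes = state0$classes,
                 final_state = st),
            class = "landcover_series")
}
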