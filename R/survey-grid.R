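#' Aggregate survey records to the modelling grid
#'
#' Averages all nest-count records falling in each grid cell over the whole
#' monitoring period (across transects and repeat years), attaches the
#' predictor values of the cell, and appends pseudoabsence rows (mean count
#' and presence fixed at 0). Cells never surveyed and not selected as
#' pseudoabsences are excluded. Presence is defined as a positive mean
#' count; observed zeros inside reserves remain "true absences" and keep
#' `source = "observed"`, distinct from pseudoabsences.
#'
#' @param survey a `nest_survey` (records plus optional pseudoabsences).
#' @param landscape the `landscape` providing predictors and grid geometry.
#' @return a `gridded_dataset`: data.frame with columns `cell_id`, `row`,
#'   `col`, `mean_count`, `n_records`, `presence`, `source` and one column
#'   per predictor; attribute `"predictors"` lists the predictor columns.
#' @export
aggregate_counts <- function(survey, landscape) {
  stopifnot(inherits(survey, "nest_survey"), inherits(landscape, "landscape"))
  rec <- survey$records
  nr <- nrow(landscape$landcover); nc <- ncol(landscape$landcover)
  off <- which(rec$row < 1 | rec$row > nr | rec$col < 1 | rec$col > nc)
  if (length(off))
    stop(sprintf("record %d at (row %d, col %d) falls off the %dx%d grid",
                 off[1], rec$row[off[1]], rec$col[off[1]], nr, nc),
         call. = FALSE)
  key <- (rec$col - 1L) * nr + rec$row
  mean_count <- tapply(rec$count, key, mean)
  n_records <- tapply(rec$count, key, length)
  cell <- as.integer(names(mean_count))
  obs <- data.frame(cell_id = cell,
                    row = ((cell - 1L) %% nr) + 1L,
                    col = ((cell - 1L) %/% nr) + 1L,
                    mean_count = as.numeric(mean_count),
                    n_records = as.integer(n_records),
                    source = "observed")
  pa <- survey$pseudoabsences
  if (nrow(pa)) {
    pa_cell <- (pa$col - 1L) * nr + pa$row
    pa_cell <- setdiff(pa_cell, cell)
    if (length(pa_cell))
      obs <- rbind(obs,
                   data.frame(cell_id = pa_cell,
                              row = ((pa_cell - 1L) %% nr) + 1L,
                              col = ((pa_cell - 1L) %/% nr) + 1L,
                              mean_count = 0, n_records = 0L,
                              source = "pseudoabsence"))
  }
  obs$presence <- as.integer(obs$mean_count > 0)
  x <- predictor_matrix(landscape)[obs$cell_id, , drop = FALSE]
  out <- cbind(obs, as.data.frame(x))
  rownames(out) <- NULL
  attr(out, "predictors") <- colnames(x)
  class(out) <- c("gridded_dataset", "data.frame")
  out
}

#' Sample pseudoabsence cells outside forest reserves
#'
#' Draws `n` unique cells uniformly without replacement from cells outside
#' reserves (and outside strictly protected areas) that were never surveyed.
#' Pseudoabsences stand in for absences in the over-degraded, unforested
#' areas the aerial surveys skipped, countering the survey's bias towards
#' reserves.
#'
#' @param landscape a `landscape`.
#' @param survey a `nest_survey`; its surveyed cells are excluded. The
#'   returned survey carries the sampled points in `$pseudoabsences`.
#' @param n number of pseudoabsence cells.
#' @param seed integer RNG seed.
#' @return the survey with `pseudoabsences` filled (data.frame `row`,
#'   `col`).
#' @export
sample_pseudoabsences <- function(landscape, survey, n, seed = 1L) {
  stopifnot(inherits(landscape, "landscape"), inherits(survey, "nest_survey"),
            n >= 0)
  nr <- nrow(landscape$landcover)
  res <- raster_values(landscape$reserve_id) > 0
  strict <- raster_values(landscape$strict_mask) > 0
  surveyed <- unique((survey$records$col - 1L) * nr + survey$records$row)
  eligible <- which(!res & !strict)
  eligible <- setdiff(eligible, surveyed)
  if (n > length(eligible))
    stop(sprintf("requested %d pseudoabsences but only %d eligible cells",
                 n, length(eligible)), call. = FALSE)
  set.seed(seed)
  pick <- if (n > 0) sample(eligible, n) else integer()
  survey$pseudoabsences <- data.frame(row = ((pick - 1L) %% nr) + 1L,
                                      col = ((pick - 1L) %/% nr) + 1L)
  survey
}

# --- Moran's I -------------------------------------------------------------

neighbor_offsets <- function(scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  if (scheme == "rook") offs <- offs[abs(offs$dr) + abs(offs$dc) == 1, ]
  offs
}

# Row-standardized spatial lag and neighbour counts for a grid field.
spatial_lag <- function(m, scheme) {
  offs <- neighbor_offsets(scheme)
  s <- matrix(0, nrow(m), ncol(m)); cnt <- s
  for (i in seq_len(nrow(offs))) {
    sh <- shift_mat(m, offs$dr[i], offs$dc[i])
    ok <- !is.na(sh)
    s[ok] <- s[ok] + sh[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  s / cnt
}

#' Global and local Moran's I on a grid field
#'
#' Spatial autocorrelation with row-standardized contiguity weights on the
#' raster grid (queen 8-neighbour by default, rook available). The global
#' statistic is the standard cross-product form
#' \eqn{I = (n/W) \sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2}; the local form is
#' \eqn{I_i = (z_i/m_2) \sum_j w_{ij} z_j} with \eqn{m_2 = \sum z^2 / n},
#' whose unweighted mean is the reported "mean local I" diagnostic used to
#' compare candidate grid resolutions.
#'
#' @param values `grid_raster` or matrix of cell values.
#' @param scheme `"queen"` or `"rook"` contiguity.
#' @return for `global_morans_i`, a `moran_result` list with `global_I`,
#'   `scheme`, `n`; for `local_morans_i`, the same plus `local_I` (matrix)
#'   and `mean_local_I`.
#' @export
global_morans_i <- function(values, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  m <- if (inherits(values, "grid_raster")) raster_values(values) else
    as.matrix(values)
  if (length(m) < 2) stop("need at least 2 cells", call. = FALSE)
  if (stats::sd(m) == 0)
    stop("Moran's I is undefined for a constant field", call. = FALSE)
  z <- m - mean(m)
  lag_z <- spatial_lag(z, scheme)
  # with row-standardized weights W = n, so n/W = 1 and I reduces to this
  i_global <- sum(z * lag_z) / sum(z^2)
  structure(list(global_I = i_global, scheme = scheme, n = length(m)),
            class = "moran_result")
}

#' @rdname global_morans_i
#' @export
local_morans_i <- function(values, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  m <- if (inherits(values, "grid_raster")) raster_values(values) else
    as.matrix(values)
  if (length(m) < 2) stop("need at least 2 cells", call. = FALSE)
  if (stats::sd(m) == 0)
    stop("Moran's I is undefined for a constant field", call. = FALSE)
  z <- m - mean(m)
  m2 <- sum(z^2) / length(z)
  local_i <- (z / m2) * spatial_lag(z, scheme)
  structure(list(global_I = sum(z * spatial_lag(z, scheme)) / sum(z^2),
                 local_I = local_i, mean_local_I = mean(local_i),
                 scheme = scheme, n = length(m)),
            class = "moran_result")
}

#' Screen predictors for pairwise Spearman correlation
#'
#' Computes all pairwise Spearman rank correlations among the dataset's
#' predictor columns and flags pairs whose absolute correlation exceeds the
#' threshold. Flagging only: whether to drop a member of a flagged pair is
#' the analyst's call (e.g. elevation and slope may both be retained on
#' ecological grounds). Constant predictors yield an undefined correlation,
#' reported as `NA` with a note.
#'
#' @param dataset a `gridded_dataset`, or a data.frame/matrix of predictors.
#' @param threshold absolute Spearman correlation above which a pair is
#'   flagged (default 0.68).
#' @return data.frame with columns `var1`, `var2`, `rho`, `flagged`,
#'   `note`.
#' @export
screen_predictors <- function(dataset, threshold = 0.68) {
  x <- if (inherits(dataset, "gridded_dataset"))
    as.matrix(dataset[, attr(dataset, "predictors"), drop = FALSE])
  else as.matrix(dataset)
  if (nrow(x) < 3) stop("need at least 3 rows", call. = FALSE)
  nm <- colnames(x)
  pairs <- utils::combn(length(nm), 2)
  out <- data.frame(var1 = nm[pairs[1, ]], var2 = nm[pairs[2, ]],
                    rho = NA_real_, flagged = FALSE, note = "")
  for (i in seq_len(ncol(pairs))) {
    a <- x[, pairs[1, i]]; b <- x[, pairs[2, i]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      out$note[i] <- "undefined: constant predictor"
      next
    }
    out$rho[i] <- stats::cor(a, b, method = "spearman")
    out$flagged[i] <- abs(out$rho[i]) > threshold
  }
  out
}
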