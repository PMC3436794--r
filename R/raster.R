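#' Minimal gridded-raster container
#'
#' A `grid_raster` is a numeric matrix carrying a square-cell geotransform:
#' lower-left corner coordinates and a cell size in km. Row 1 is the north
#' edge of the grid (the usual raster convention); column 1 the west edge.
#' All layers of a landscape share one geometry, which every operation in the
#' package validates before combining layers.
#'
#' @param values numeric matrix of cell values.
#' @param cellsize cell side length in km (> 0).
#' @param xll,yll coordinates of the lower-left corner (km).
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(values, cellsize = 2.5, xll = 0, yll = 0) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values), cellsize > 0)
  if (is.logical(values)) storage.mode(values) <- "integer"
  structure(values,
            cellsize = cellsize, xll = xll, yll = yll,
            class = c("grid_raster", "matrix", "array"))
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells, cellsize %g km, origin (%g, %g)\n",
              nrow(x), ncol(x), attr(x, "cellsize"), attr(x, "xll"),
              attr(x, "yll")))
  cat(sprintf("  values: min %g, mean %g, max %g\n",
              min(x), mean(x), max(x)))
  invisible(x)
}

raster_values <- function(x) {
  a <- unclass(x)
  attr(a, "cellsize") <- NULL
  attr(a, "xll") <- NULL
  attr(a, "yll") <- NULL
  a
}

#' Check that two rasters share geometry
#'
#' @param a,b `grid_raster` objects or plain matrices.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b) {
  isTRUE(all(dim(a) == dim(b))) &&
    isTRUE(all.equal(attr(a, "cellsize") %||% NA_real_,
                     attr(b, "cellsize") %||% NA_real_)) &&
    isTRUE(all.equal(attr(a, "xll") %||% 0, attr(b, "xll") %||% 0)) &&
    isTRUE(all.equal(attr(a, "yll") %||% 0, attr(b, "yll") %||% 0))
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!isTRUE(all(dim(a) == dim(b))))
    stop(sprintf("%s are misaligned: shapes %dx%d vs %dx%d", what,
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text single-band raster I/O. Values are written at full double
#' precision (`%.17g`) so a write/read round trip is bit-exact; integer
#' layers (land-cover classes, masks) round trip exactly by construction.
#' `NA` cells are stored as the nodata value.
#'
#' @param path file path, conventionally with extension `.asc`.
#' @param x a `grid_raster`.
#' @param nodata numeric nodata sentinel written to the header.
#' @return `read_asc` returns a `grid_raster`; `write_asc` returns `path`
#'   invisibly.
#' @export
write_asc <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "grid_raster"))
  v <- raster_values(x)
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", attr(x, "xll")),
    sprintf("yllcorner %.10g", attr(x, "yll")),
    sprintf("cellsize %.17g", attr(x, "cellsize")),
    sprintf("NODATA_value %.10g", nodata)), con)
  # row 1 of the matrix is the north edge, matching the .asc convention
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " ")), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- scan(text = body, quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid_raster(m, cellsize = hdr$cellsize,
              xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0)
}
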