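#' Lightweight georeferenced raster grid
#'
#' A `raster_grid` stores a single band as a numeric matrix in geographic
#' (lon/lat, WGS84) coordinates with cell-center registration. Row 1 is the
#' northernmost row; `NA` cells are nodata. This is the container every raster
#' operation in the package consumes and returns.
#'
#' @param values numeric matrix (rows = latitude bands, north at row 1).
#' @param xmin,ymax western edge and northern edge of the grid, decimal degrees.
#' @param res cell size in decimal degrees (square cells).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymax, res) {
  stopifnot(is.matrix(values), res > 0)
  structure(
    list(values = values, xmin = xmin, ymax = ymax, res = res,
         nrow = nrow(values), ncol = ncol(values)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf(
    "raster_grid: %d x %d cells, res %g deg\n  extent: lon [%g, %g], lat [%g, %g]\n  values: [%g, %g], %d nodata\n",
    x$nrow, x$ncol, x$res, x$xmin, x$xmin + x$ncol * x$res,
    x$ymax - x$nrow * x$res, x$ymax, rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Cell-center coordinates of every cell
#'
#' @param g a `raster_grid`.
#' @return matrix with columns `lon`, `lat`, in matrix-element order
#'   (column-major over the value matrix).
#' @export
rg_coords <- function(g) {
  lon <- g$xmin + (seq_len(g$ncol) - 0.5) * g$res
  lat <- g$ymax - (seq_len(g$nrow) - 0.5) * g$res
  cbind(lon = rep(lon, each = g$nrow), lat = rep(lat, times = g$ncol))
}

#' Row/column of the cell containing each point
#'
#' Points on the grid edge snap inward so that any point inside the extent
#' maps to a valid cell.
#'
#' @param g a `raster_grid`.
#' @param lon,lat point coordinates, decimal degrees.
#' @return integer matrix with columns `row`, `col`; `NA` for points outside
#'   the extent.
#' @export
rg_cell <- function(g, lon, lat) {
  col <- floor((lon - g$xmin) / g$res) + 1L
  row <- floor((g$ymax - lat) / g$res) + 1L
  col[col == g$ncol + 1L & lon <= g$xmin + g$ncol * g$res] <- g$ncol
  row[row == g$nrow + 1L & lat >= g$ymax - g$nrow * g$res] <- g$nrow
  bad <- col < 1L | col > g$ncol | row < 1L | row > g$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Extract raster values at point locations
#'
#' @inheritParams rg_cell
#' @return numeric vector; `NA` where the point is outside the extent or on a
#'   nodata cell.
#' @export
rg_extract <- function(g, lon, lat) {
  rc <- rg_cell(g, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(rc[, 1])
  out[ok] <- g$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Check that rasters share one grid
#'
#' Same shape, extent, resolution and nodata mask.
#'
#' @param ... `raster_grid` objects (or a single list of them).
#' @return `TRUE` invisibly; stops otherwise.
#' @export
rg_check_aligned <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1]], "raster_grid")) gs <- gs[[1]]
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (g$nrow != ref$nrow || g$ncol != ref$ncol ||
        abs(g$xmin - ref$xmin) > 1e-9 || abs(g$ymax - ref$ymax) > 1e-9 ||
        abs(g$res - ref$res) > 1e-12)
      stop("rasters do not share extent/resolution")
    if (!identical(is.na(g$values), is.na(ref$values)))
      stop("rasters do not share a nodata mask")
  }
  invisible(TRUE)
}

# Same shape, extent and resolution (nodata masks may differ).
rg_check_shape <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1]], "raster_grid")) gs <- gs[[1]]
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (g$nrow != ref$nrow || g$ncol != ref$ncol ||
        abs(g$xmin - ref$xmin) > 1e-9 || abs(g$ymax - ref$ymax) > 1e-9 ||
        abs(g$res - ref$res) > 1e-12)
      stop("rasters do not share extent/resolution")
  }
  invisible(TRUE)
}

#' Aggregate a raster to a coarser resolution
#'
#' The target resolution must be an integer multiple of the source resolution
#' and the extents must line up. Used by the weighted overlay to upscale
#' elevation (mean) and river (max) layers to the climate grid.
#'
#' @param g a `raster_grid`.
#' @param factor integer block size.
#' @param fun aggregation function over each block (`NA` removed; all-`NA`
#'   blocks stay `NA`).
#' @return a coarser `raster_grid`.
#' @export
rg_aggregate <- function(g, factor, fun = mean) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1, g$nrow %% factor == 0, g$ncol %% factor == 0)
  if (factor == 1L) return(g)
  nr <- g$nrow %/% factor; nc <- g$ncol %/% factor
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    block <- g$values[((i - 1) * factor + 1):(i * factor),
                      ((j - 1) * factor + 1):(j * factor)]
    v <- block[!is.na(block)]
    if (length(v)) out[i, j] <- fun(v)
  }
  raster_grid(out, g$xmin, g$ymax, g$res * factor)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols/nrows/xllcorner/yllcorner/cellsize`
#' header, then rows north to south, nodata as -9999).
#'
#' @param g a `raster_grid`.
#' @param path file path.
#' @export
write_ascii_grid <- function(g, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymax - g$nrow * g$res),
    sprintf("cellsize %.10g", g$res), "NODATA_value -9999"), con)
  v <- g$values; v[is.na(v)] <- -9999
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, as.is = TRUE)
  val <- stats::setNames(as.numeric(hdr[[2]]), tolower(hdr[[1]]))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA
  raster_grid(v, val[["xllcorner"]],
              val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]],
              val[["cellsize"]])
}
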