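#' Elevation preference curve from occurrences
#'
#' Bins the DEM elevations observed at occurrence localities into
#' `bin_width_m`-wide intervals and rescales the raw occurrence frequencies
#' to a 1-to-10 preference score:
#' `value = 1 + round_half_up(9 * (count - min) / (max - min))` over the bins
#' spanning the occupied elevation range (zero-count bins inside the range
#' included). If all counts are equal the occupied bins score 10. Bins beyond
#' the occupied range score 1.
#'
#' @param occ data.frame of occurrences (`lon`, `lat`).
#' @param dem elevation `raster_grid` (m a.s.l.).
#' @param bin_width_m bin width in metres (default 100).
#' @return object of class `elevation_preference`: `bin_edges` (length
#'   `n_bins + 1`), `bin_values` (integers 1-10), `counts`.
#' @export
elevation_preference_curve <- function(occ, dem, bin_width_m = 100) {
  if (NROW(occ) == 0) stop("no occurrences")
  elev <- rg_extract(dem, occ$lon, occ$lat)
  elev <- elev[!is.na(elev)]
  if (length(elev) == 0) stop("no occurrences on valid DEM cells")
  lo <- floor(min(elev) / bin_width_m) * bin_width_m
  hi <- ceiling((max(elev) + 1e-9) / bin_width_m) * bin_width_m
  if (hi <= lo) hi <- lo + bin_width_m
  edges <- seq(lo, hi, by = bin_width_m)
  counts <- as.vector(table(cut(elev, edges, include.lowest = TRUE,
                                right = FALSE)))
  rng <- max(counts) - min(counts)
  values <- if (rng == 0) rep(10L, length(counts))
            else as.integer(1 + round_half_up(9 * (counts - min(counts)) / rng))
  structure(list(bin_edges = edges, bin_values = values, counts = counts),
            class = "elevation_preference")
}

#' Reclassify a DEM by an elevation preference curve
#'
#' @param pref an [elevation_preference_curve()] result.
#' @param dem elevation `raster_grid`.
#' @return `raster_grid` of preference classes 1-10 (elevations outside the
#'   occupied range get 1; nodata preserved).
#' @export
apply_elevation_preference <- function(pref, dem) {
  v <- dem$values
  ok <- !is.na(v)
  out <- v
  idx <- findInterval(v[ok], pref$bin_edges, rightmost.closed = TRUE)
  val <- rep(1L, sum(ok))
  inside <- idx >= 1 & idx <= length(pref$bin_values)
  val[inside] <- pref$bin_values[idx[inside]]
  out[ok] <- val
  raster_grid(out, dem$xmin, dem$ymax, dem$res)
}

#' River connectivity-functionality index raster
#'
#' Keeps river segments with Strahler order above `order_threshold` (the
#' major watercourses), scores each as `CSI - URB` (connectivity status minus
#' urbanization pressure, both percentages), min-max rescales the retained
#' scores to 1-10 (round half up), and rasterizes: a cell takes the maximum
#' score of the segments crossing it; cells without rivers get 1.
#'
#' @param rivers list of segments (`coords` matrix, `strahler_order`, `CSI`,
#'   `URB`), as produced by [generate_rivers_forests_protected()].
#' @param template `raster_grid` defining the output grid.
#' @param order_threshold keep segments with `strahler_order >` this
#'   (default 4).
#' @return `raster_grid` of integers 1-10.
#' @export
river_functionality_index <- function(rivers, template, order_threshold = 4) {
  keep <- Filter(function(r) r$strahler_order > order_threshold, rivers)
  out <- matrix(1, template$nrow, template$ncol)
  if (length(keep) == 0) {
    warning("no river segments above the Strahler order threshold")
  } else {
    raw <- vapply(keep, function(r) r$CSI - r$URB, numeric(1))
    rng <- max(raw) - min(raw)
    cls <- if (rng == 0) rep(10, length(raw))
           else 1 + round_half_up(9 * (raw - min(raw)) / rng)
    for (i in seq_along(keep)) {
      pts <- densify(keep[[i]]$coords, template$res / 2)
      rc <- rg_cell(template, pts[, 1], pts[, 2])
      rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
      if (nrow(rc))
        out[unique(rc, MARGIN = 1)] <-
          pmax(out[unique(rc, MARGIN = 1)], cls[i])
    }
  }
  out[is.na(template$values)] <- NA
  raster_grid(out, template$xmin, template$ymax, template$res)
}

#' Convert an old-growth forest point to a polygon
#'
#' The forest's radius follows from its area:
#' `radius_m = sqrt(area_ha * 10000 / pi)`; a geodesic buffer of that radius
#' is drawn around the point, then refined by dropping the buffer cells where
#' `forest_mask` is FALSE (no mask keeps the whole disk).
#'
#' @param lon,lat forest point, decimal degrees.
#' @param area_ha forest area in hectares (> 0).
#' @param forest_mask optional logical-valued `raster_grid` (TRUE = forest).
#' @param category optional category label carried through.
#' @param n_vertices vertices of the buffer ring (default 90).
#' @return object of class `forest_polygon`: `center`, `radius_m`, `ring`
#'   (lon/lat matrix), `cells` (kept mask cells, row/col), `area_ha`,
#'   `refined_area_ha`, `category`.
#' @export
forest_point_to_polygon <- function(lon, lat, area_ha, forest_mask = NULL,
                                    category = NA_character_,
                                    n_vertices = 90L) {
  if (area_ha <= 0) stop("forest area must be positive")
  radius_m <- sqrt(area_ha * 10000 / pi)
  ring <- geosphere::destPoint(c(lon, lat), b = seq(0, 360, length.out =
                                                      n_vertices + 1L),
                               d = radius_m, r = EARTH_RADIUS_M)
  colnames(ring) <- c("lon", "lat")
  cells <- NULL; refined_area_ha <- area_ha
  if (!is.null(forest_mask)) {
    xy <- rg_coords(forest_mask)
    inside <- gc_distance_km(c(lon, lat), xy) <= radius_m / 1000
    keep <- inside & !is.na(as.vector(forest_mask$values)) &
      as.vector(forest_mask$values) > 0
    ij <- arrayInd(which(keep), c(forest_mask$nrow, forest_mask$ncol))
    cells <- cbind(row = ij[, 1], col = ij[, 2])
    cell_km2 <- (forest_mask$res * pi / 180 * EARTH_RADIUS_M / 1000)^2 *
      cos(xy[keep, 2] * pi / 180)
    refined_area_ha <- sum(cell_km2) * 100
  }
  structure(list(center = c(lon = lon, lat = lat), radius_m = radius_m,
                 ring = ring, cells = cells, area_ha = area_ha,
                 refined_area_ha = refined_area_ha, category = category),
            class = "forest_polygon")
}

#' Weighted habitat-suitability overlay
#'
#' Cell-by-cell weighted sum of the three 1-to-10 layers (reclassified
#' climate suitability, elevation preference, river functionality), rounded
#' half up back to an integer 1-10. Elevation and river layers on a finer
#' grid are upscaled to the climate resolution first (mean aggregation for
#' elevation classes, max for river classes). Nodata in the climate layer
#' propagates.
#'
#' @param climate,elevation,rivers `raster_grid`s with integer values 1-10.
#' @param weights three non-negative weights summing to 1 (climate,
#'   elevation, rivers); default `c(0.5, 0.25, 0.25)`.
#' @return `raster_grid` of weighted suitability classes 1-10.
#' @export
weighted_overlay <- function(climate, elevation, rivers,
                             weights = c(0.5, 0.25, 0.25)) {
  stopifnot(length(weights) == 3, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  upscale <- function(g, fun) {
    if (abs(g$res - climate$res) < 1e-12) return(g)
    f <- climate$res / g$res
    if (abs(f - round(f)) > 1e-9 || f < 1)
      stop("layer resolution must be an integer refinement of the climate grid")
    rg_aggregate(g, round(f), fun)
  }
  elevation <- upscale(elevation, mean)
  rivers <- upscale(rivers, max)
  rg_check_aligned2 <- function(a, b)  # alignment only; masks may differ
    stopifnot(a$nrow == b$nrow, a$ncol == b$ncol,
              abs(a$xmin - b$xmin) < 1e-9, abs(a$ymax - b$ymax) < 1e-9)
  rg_check_aligned2(climate, elevation); rg_check_aligned2(climate, rivers)
  v <- weights[1] * climate$values + weights[2] * elevation$values +
    weights[3] * rivers$values
  out <- pmin(pmax(round_half_up(v), 1), 10)
  out[is.na(climate$values)] <- NA
  raster_grid(out, climate$xmin, climate$ymax, climate$res)
}

#' Sweep overlay weights for sensitivity analysis
#'
#' Recomputes the weighted overlay over a grid of weight triples and reports,
#' for each, the mean class and the fraction of cells whose class changes
#' relative to the default weighting.
#'
#' @inheritParams weighted_overlay
#' @param step grid step over the weight simplex (default 0.25).
#' @return data.frame with `w_climate`, `w_elevation`, `w_rivers`,
#'   `mean_class`, `frac_changed`.
#' @export
overlay_weight_sweep <- function(climate, elevation, rivers, step = 0.25) {
  ref <- weighted_overlay(climate, elevation, rivers)
  ws <- seq(0, 1, by = step)
  out <- list()
  for (wc in ws) for (we in ws) {
    wr <- 1 - wc - we
    if (wr < -1e-9) next
    wr <- max(wr, 0)
    o <- weighted_overlay(climate, elevation, rivers, c(wc, we, wr))
    out[[length(out) + 1L]] <- data.frame(
      w_climate = wc, w_elevation = we, w_rivers = wr,
      mean_class = mean(o$values, na.rm = TRUE),
      frac_changed = mean(o$values != ref$values, na.rm = TRUE))
  }
  do.call(rbind, out)
}
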