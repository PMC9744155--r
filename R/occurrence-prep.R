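#' Filter raw occurrence records
#'
#' Applies, in order, the three record-quality rules used to clean
#' presence-only datasets before niche modelling:
#' \enumerate{
#'   \item drop records older than `min_year` (records with a missing year are
#'     kept, since the rule only excludes records known to predate the cutoff);
#'   \item drop records whose coordinate precision implies a positional
#'     uncertainty coarser than `max_coord_error_arcmin`. Uncertainty is
#'     `0.5 * 10^-decimals` degrees, with `decimals` taken from a
#'     `coord_decimals` column when present, else from the printed coordinates;
#'   \item deduplicate records sharing a grid cell of `cell_size` degrees
#'     (first record wins).
#' }
#'
#' @param raw data.frame with columns `lon`, `lat` and optionally `year`,
#'   `source`, `coord_decimals`.
#' @param min_year records with `year < min_year` are dropped (default 1970).
#' @param max_coord_error_arcmin maximum tolerated positional uncertainty, in
#'   arc-minutes (default 2.5).
#' @param cell_size deduplication cell size in decimal degrees
#'   (default 2.5/60, i.e. 2.5 arc-min).
#' @return list with `records` (the retained data.frame) and `drop_counts`
#'   (named integer vector: `year`, `precision`, `duplicate`). Empty input
#'   yields an empty frame with zeroed counts.
#' @export
filter_records <- function(raw, min_year = 1970,
                           max_coord_error_arcmin = 2.5,
                           cell_size = 2.5 / 60) {
  stopifnot(cell_size > 0)
  counts <- c(year = 0L, precision = 0L, duplicate = 0L)
  if (NROW(raw) == 0)
    return(list(records = raw, drop_counts = counts))
  keep <- rep(TRUE, nrow(raw))
  if (!is.null(raw$year)) {
    old <- !is.na(raw$year) & raw$year < min_year
    counts["year"] <- sum(old)
    keep <- keep & !old
  }
  dec <- if (!is.null(raw$coord_decimals)) raw$coord_decimals
         else pmin(decimal_places(raw$lon), decimal_places(raw$lat))
  uncertainty_deg <- 0.5 * 10^(-dec)
  coarse <- keep & uncertainty_deg > max_coord_error_arcmin / 60
  counts["precision"] <- sum(coarse)
  keep <- keep & !coarse
  cell <- paste(floor(raw$lon / cell_size), floor(raw$lat / cell_size))
  idx <- which(keep)  # deduplicate among records that survived the other rules
  dup <- rep(FALSE, nrow(raw))
  dup[idx[duplicated(cell[idx])]] <- TRUE
  counts["duplicate"] <- sum(dup)
  keep <- keep & !dup
  list(records = raw[keep, , drop = FALSE], drop_counts = counts)
}

#' Pairwise inter-point distance summary
#'
#' Mean and median distance over all unordered pairs of records, in km.
#' Distances are great-circle by default (haversine on a sphere of radius
#' 6371.0088 km); `method = "planar"` treats lon/lat as planar coordinates
#' and multiplies degree distances by 111.195 km/deg.
#'
#' @param occ data.frame with `lon`, `lat` (>= 2 rows).
#' @param method `"greatcircle"` (default) or `"planar"`.
#' @return list with `mean_km`, `median_km`, `n_pairs`.
#' @export
pairwise_distance_stats <- function(occ, method = c("greatcircle", "planar")) {
  method <- match.arg(method)
  if (NROW(occ) < 2) stop("need at least 2 records")
  pts <- cbind(occ$lon, occ$lat)
  if (method == "greatcircle") {
    d <- gc_distance_matrix_km(pts)
    d <- d[upper.tri(d)]
  } else {
    d <- as.vector(stats::dist(pts)) * pi / 180 * EARTH_RADIUS_M / 1000
  }
  list(mean_km = mean(d), median_km = stats::median(d), n_pairs = length(d))
}

#' Assign longitude groups to occurrence records
#'
#' Records are labelled by the half-open interval `[break_i, break_{i+1})`
#' containing their longitude. The defaults split the western Palearctic into
#' West (-15 to 0), Central (0 to 15) and East (15 to 50); interval edges
#' belong to the interval on their right.
#'
#' @param occ data.frame with `lon`.
#' @param breaks strictly increasing break longitudes (length = groups + 1).
#' @param labels group labels (length = `length(breaks) - 1`).
#' @return `occ` with a `group` column; records outside `[first, last)` get
#'   `"outside"` and a warning reports their count.
#' @export
assign_longitude_groups <- function(occ, breaks = c(-15, 0, 15, 50),
                                    labels = c("West", "Central", "East")) {
  stopifnot(all(diff(breaks) > 0), length(labels) == length(breaks) - 1)
  idx <- findInterval(occ$lon, breaks, rightmost.closed = FALSE)
  grp <- rep("outside", NROW(occ))
  inside <- idx >= 1 & idx <= length(labels) &
    occ$lon >= breaks[1] & occ$lon < breaks[length(breaks)]
  grp[inside] <- labels[idx[inside]]
  n_out <- sum(!inside)
  if (n_out > 0)
    warning(sprintf("%d record(s) outside the longitude breaks labelled 'outside'",
                    n_out))
  occ$group <- grp
  occ
}
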