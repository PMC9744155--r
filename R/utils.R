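# Internal helpers shared across modules.

# Mean Earth radius (m); all great-circle distances in the package use it.
EARTH_RADIUS_M <- 6371008.8

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param p1,p2 two-column matrices (lon, lat) or length-2 vectors.
#' @return distance(s) in km.
#' @export
gc_distance_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M) / 1000
}

# Full pairwise great-circle distance matrix (km) for a lon/lat matrix.
gc_distance_matrix_km <- function(pts) {
  n <- nrow(pts)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    d[i, (i + 1):n] <- gc_distance_km(pts[i, , drop = FALSE],
                                      pts[(i + 1):n, , drop = FALSE])
  }
  d + t(d)
}

# Round half away from zero at .5 (the GIS convention used by the 1-10 layers),
# unlike base round()'s round-half-even.
round_half_up <- function(x) floor(x + 0.5)

# Separable Gaussian smoothing of a matrix; edge effects handled by
# renormalising the kernel mass that falls inside the matrix.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    k <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma)
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# Number of decimal places in the printed form of a coordinate (capped at 10).
decimal_places <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_integer_)
    s <- format(v, scientific = FALSE, trim = TRUE, digits = 10)
    dot <- regexpr(".", s, fixed = TRUE)
    if (dot < 0) return(0L)
    frac <- sub("0+$", "", substring(s, dot + 1))
    nchar(frac)
  }, integer(1))
}

# Points-in-polygon over a list of rings (each a closed two-column matrix).
# Returns logical: inside any ring.
in_any_polygon <- function(pts, rings) {
  inside <- rep(FALSE, nrow(pts))
  for (r in rings) {
    r <- close_ring(r)
    inside <- inside | mgcv::in.out(r, pts)
  }
  inside
}

# Ensure a polygon ring is closed (first vertex repeated at the end).
close_ring <- function(r) {
  r <- as.matrix(r)
  if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
  r
}

# Densify a polyline/ring so consecutive vertices are at most step_deg apart.
densify <- function(coords, step_deg) {
  coords <- as.matrix(coords)
  out <- list()
  for (i in seq_len(nrow(coords) - 1)) {
    a <- coords[i, ]; b <- coords[i + 1, ]
    nseg <- max(1L, ceiling(max(abs(b - a)) / step_deg))
    t <- seq(0, 1, length.out = nseg + 1L)[-(nseg + 1L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  rbind(do.call(rbind, out), coords[nrow(coords), , drop = FALSE])
}
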