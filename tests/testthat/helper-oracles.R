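# Shared fixtures and independent oracles used across the suite.

# One small landscape, generated once per test run.
small_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_landscape(extent = c(-10, 10, 35, 55),
                                   resolution = 0.5,
                                   truth = synthetic_truth(
                                     seed = 42, beta = c(2, -1, 0.5)),
                                   n_occ = 150)
    cache
  }
})

# Dense-matrix effective resistance between two node ids, via the
# Moore-Penrose pseudo-inverse of the full Laplacian (independent of the
# package's sparse reduced-system solve).
dense_resistance_oracle <- function(cg, s, t) {
  n <- nrow(cg$nodes)
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(cg$edges))) {
    i <- cg$edges$i[k]; j <- cg$edges$j[k]; g <- cg$edges$g[k]
    L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
  }
  Lp <- MASS::ginv(L)
  e <- numeric(n); e[s] <- 1; e[t] <- -1
  drop(t(e) %*% Lp %*% e)
}

# Direct per-definition MESS similarity for one value against a reference.
mess_oracle <- function(p, ref) {
  f <- 100 * sum(ref < p) / length(ref)
  rmin <- min(ref); rmax <- max(ref)
  if (f == 0) 100 * (p - rmin) / (rmax - rmin)
  else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else 100 * (rmax - p) / (rmax - rmin)
}

# Textbook global Moran's I for a weight matrix W (zero diagonal).
moran_oracle <- function(x, W) {
  n <- length(x); z <- x - mean(x)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

# A flat conductance raster of the given shape (degrees arbitrary).
uniform_ws <- function(nrow, ncol, value = 1, res = 1) {
  raster_grid(matrix(value, nrow, ncol), 0, nrow * res, res)
}

# Focal data.frame addressing cells (row, col) of a raster by their centers.
cell_points <- function(g, rows, cols) {
  data.frame(lon = g$xmin + (cols - 0.5) * g$res,
             lat = g$ymax - (rows - 0.5) * g$res)
}

# Concentric ring and inner disk in 2-D: inseparable by any hyperplane,
# separable by a quadric.
ring_disk_sets <- function(n = 60, seed = 23) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  ring <- cbind(x = (3 + runif(n, 0, 0.5)) * cos(th),
                y = (3 + runif(n, 0, 0.5)) * sin(th))
  disk <- cbind(x = runif(n, -1, 1), y = runif(n, -1, 1))
  list(ring = ring, disk = disk)
}
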