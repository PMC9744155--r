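#' Ground truth for a synthetic landscape
#'
#' Bundles every knob of the synthetic-landscape generator together with the
#' true occurrence-generating model, so that recovery tests can compare what a
#' fitted model found against what was actually simulated.
#'
#' Predictor surfaces are spatially autocorrelated fields (Gaussian-filtered
#' white noise plus a latitudinal gradient), standing in for interpolated
#' bioclimatic climatologies. Occurrence probability over the landscape is
#' `plogis(intercept + beta %*% predictors)`. Future climates are the current
#' surfaces plus a per-GCM additive trend (scaled by the horizon's position in
#' `years`, so later horizons drift further) plus spatial noise.
#'
#' @param seed integer; every generator derives its RNG stream from it.
#' @param beta numeric vector of true coefficients, one per predictor.
#' @param intercept scalar intercept of the occurrence model.
#' @param collinear_pairs list of `c(i, j, rho)` triples: predictor `j` is
#'   rebuilt so that `cor(P_i, P_j)` equals `rho` (|rho| <= 1).
#' @param gcm_shift matrix (n_gcm x n_predictors) or vector recycled across
#'   GCMs: additive trend per predictor, in predictor units per horizon step.
#' @param gcm_noise_sd per-GCM standard deviation of the added spatial noise.
#' @param gcms character labels of the synthetic GCMs.
#' @param ssps,years the scenario axes of the future stacks.
#' @param smooth_sigma Gaussian filter standard deviation, in cells.
#' @param lat_gradient weight of the north-south gradient added to each field.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1L,
                            beta = c(2, -1, 0.5),
                            intercept = 0,
                            collinear_pairs = list(),
                            gcm_shift = 0.3,
                            gcm_noise_sd = 0.1,
                            gcms = c("GCM-A", "GCM-B", "GCM-C"),
                            ssps = c("ssp370", "ssp585"),
                            years = c(2030, 2050, 2070),
                            smooth_sigma = 5,
                            lat_gradient = 0.5) {
  p <- length(beta)
  if (is.null(dim(gcm_shift)))
    gcm_shift <- matrix(gcm_shift, length(gcms), p)
  stopifnot(nrow(gcm_shift) == length(gcms), ncol(gcm_shift) == p)
  gcm_noise_sd <- rep_len(gcm_noise_sd, length(gcms))
  for (cp in collinear_pairs)
    stopifnot(length(cp) == 3, abs(cp[3]) <= 1, cp[1] != cp[2],
              cp[1] >= 1, cp[2] <= p)
  structure(list(seed = as.integer(seed), beta = beta, intercept = intercept,
                 collinear_pairs = collinear_pairs, gcm_shift = gcm_shift,
                 gcm_noise_sd = gcm_noise_sd, gcms = gcms, ssps = ssps,
                 years = years, smooth_sigma = smooth_sigma,
                 lat_gradient = lat_gradient),
            class = "synthetic_truth")
}

# One standardized autocorrelated field on an nr x nc grid, plus gradient.
random_field <- function(nr, nc, sigma, lat_gradient) {
  f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  f <- (f - mean(f)) / stats::sd(f)
  if (lat_gradient != 0) {
    g <- matrix(rep(scale(seq_len(nr))[, 1], nc), nr, nc)
    f <- (f + lat_gradient * g) / sqrt(1 + lat_gradient^2)
  }
  f
}

#' Generate a synthetic predictor stack and its future counterparts
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param resolution cell size in decimal degrees.
#' @param n_predictors number of predictor layers (>= 2).
#' @param truth a [synthetic_truth()] object; `length(truth$beta)` must equal
#'   `n_predictors`.
#' @return list with `current` (named list of `raster_grid`, `P1..Pk`) and
#'   `future` (named list, one entry per `ssp|year|gcm` combination, each a
#'   predictor stack on the same grid).
#' @export
generate_environment <- function(extent, resolution, n_predictors, truth) {
  stopifnot(n_predictors >= 2, resolution > 0,
            length(truth$beta) == n_predictors)
  nc <- round((extent[2] - extent[1]) / resolution)
  nr <- round((extent[4] - extent[3]) / resolution)
  if (nr < 1 || nc < 1) stop("degenerate extent: zero cells")
  set.seed(truth$seed)
  fields <- lapply(seq_len(n_predictors), function(i)
    random_field(nr, nc, truth$smooth_sigma, truth$lat_gradient))
  # Enforce requested collinearity exactly: replace field j by
  # rho * std(P_i) + sqrt(1-rho^2) * std(residual of P_j on P_i).
  for (cp in truth$collinear_pairs) {
    i <- cp[1]; j <- cp[2]; rho <- cp[3]
    a <- as.vector(fields[[i]]); b <- as.vector(fields[[j]])
    res <- stats::residuals(stats::lm(b ~ a))
    mix <- rho * scale(a)[, 1] + sqrt(1 - rho^2) * scale(res)[, 1]
    fields[[j]] <- matrix(mix, nr, nc)
  }
  mk <- function(v) raster_grid(v, extent[1], extent[4], resolution)
  current <- stats::setNames(lapply(fields, mk),
                             paste0("P", seq_len(n_predictors)))
  future <- list()
  for (ssp in truth$ssps) for (yi in seq_along(truth$years)) {
    for (gi in seq_along(truth$gcms)) {
      stack <- lapply(seq_len(n_predictors), function(k) {
        v <- fields[[k]] + yi * truth$gcm_shift[gi, k]
        if (truth$gcm_noise_sd[gi] > 0) {
          noise <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                                   truth$smooth_sigma)
          v <- v + noise / stats::sd(noise) * truth$gcm_noise_sd[gi]
        }
        mk(v)
      })
      names(stack) <- names(current)
      future[[paste(ssp, truth$years[yi], truth$gcms[gi], sep = "|")]] <- stack
    }
  }
  list(current = current, future = future)
}

#' Sample occurrences from the true suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to the
#' logistic suitability `plogis(intercept + beta . predictors)`; each record
#' is jittered uniformly inside its cell and given a random year in
#' 1990-2020 and a source label, so the records pass the default
#' [filter_records()] rules.
#'
#' @param stack named list of predictor `raster_grid`s (the current stack).
#' @param truth a [synthetic_truth()].
#' @param n number of records (>= 1).
#' @param seed RNG seed for the draw (distinct from `truth$seed`).
#' @return data.frame with columns `lon`, `lat`, `year`, `source`.
#' @export
sample_true_occurrences <- function(stack, truth, n, seed = truth$seed + 1L) {
  stopifnot(n >= 1)
  g <- stack[[1]]
  X <- sapply(stack, function(s) as.vector(s$values))
  valid <- stats::complete.cases(X)
  if (!any(valid)) stop("all cells are nodata")
  eta <- truth$intercept + as.vector(X[valid, , drop = FALSE] %*% truth$beta)
  prob <- stats::plogis(eta)
  set.seed(seed)
  pick <- sample(which(valid), n, replace = TRUE, prob = prob)
  xy <- rg_coords(g)[pick, , drop = FALSE]
  jit <- matrix(stats::runif(2 * n, -0.45, 0.45) * g$res, n, 2)
  data.frame(lon = xy[, 1] + jit[, 1], lat = xy[, 2] + jit[, 2],
             year = sample(1990:2020, n, replace = TRUE),
             source = sample(c("literature", "gbif"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate synthetic rivers, old-growth forest points and protected areas
#'
#' Rivers are random-walk polylines with Strahler order 1-8 (both sides of the
#' order-4 selection threshold are always represented), a connectivity status
#' index (CSI) and an urbanization pressure (URB), both percentages. Forest
#' points carry log-uniform areas in 1-10000 ha and a category label.
#' Protected areas are rectangles; at least one polygon of each kind
#' (`natura2000`, `national`, `both`) is produced.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`.
#' @param truth a [synthetic_truth()] (only its seed is used).
#' @param n_rivers,n_forests,n_protected component counts.
#' @return list with `rivers` (list of segments: `coords` matrix plus
#'   `strahler_order`, `CSI`, `URB`), `forests` (data.frame `lon`, `lat`,
#'   `area_ha`, `category`) and `protected` (list of `coords` ring + `kind`).
#' @export
generate_rivers_forests_protected <- function(extent, truth,
                                              n_rivers = 12L,
                                              n_forests = 15L,
                                              n_protected = 6L) {
  set.seed(truth$seed + 7L)
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  orders <- c(3L, 5L, sample(1:8, max(0L, n_rivers - 2L), replace = TRUE))
  rivers <- lapply(seq_len(n_rivers), function(i) {
    start <- c(stats::runif(1, extent[1], extent[2]),
               stats::runif(1, extent[3], extent[4]))
    nseg <- sample(4:8, 1)
    steps <- matrix(stats::rnorm(2 * nseg, 0, 0.04 * min(w, h)), ncol = 2)
    coords <- apply(rbind(start, steps), 2, cumsum)
    coords[, 1] <- pmin(pmax(coords[, 1], extent[1]), extent[2])
    coords[, 2] <- pmin(pmax(coords[, 2], extent[3]), extent[4])
    list(coords = coords, strahler_order = orders[i],
         CSI = stats::runif(1, 0, 100), URB = stats::runif(1, 0, 100))
  })
  forests <- data.frame(
    lon = stats::runif(n_forests, extent[1] + 0.05 * w, extent[2] - 0.05 * w),
    lat = stats::runif(n_forests, extent[3] + 0.05 * h, extent[4] - 0.05 * h),
    area_ha = 10^stats::runif(n_forests, 0, 4),
    category = sample(c("Near-virgin Forest", "Old-Growth Forest",
                        "Long Untouched Forest"), n_forests, replace = TRUE),
    stringsAsFactors = FALSE)
  kinds <- c("natura2000", "national", "both",
             sample(c("natura2000", "national", "both"),
                    max(0L, n_protected - 3L), replace = TRUE))
  protected <- lapply(seq_len(max(3L, n_protected)), function(i) {
    cx <- stats::runif(1, extent[1] + 0.1 * w, extent[2] - 0.1 * w)
    cy <- stats::runif(1, extent[3] + 0.1 * h, extent[4] - 0.1 * h)
    dx <- stats::runif(1, 0.03, 0.10) * w; dy <- stats::runif(1, 0.03, 0.10) * h
    ring <- cbind(c(cx - dx, cx + dx, cx + dx, cx - dx, cx - dx),
                  c(cy - dy, cy - dy, cy + dy, cy + dy, cy - dy))
    list(coords = ring, kind = kinds[i])
  })
  list(rivers = rivers, forests = forests, protected = protected)
}

#' Generate a complete synthetic landscape bundle
#'
#' Convenience wrapper tying the generators together: predictors (current and
#' future), a DEM (smooth non-negative elevation field, m a.s.l.), rivers,
#' forests, protected areas, and `n_occ` true occurrences.
#'
#' @inheritParams generate_environment
#' @param n_occ number of occurrence records.
#' @return list with `truth`, `current`, `future`, `dem`, `rivers`,
#'   `forests`, `protected`, `occurrences`.
#' @export
generate_landscape <- function(extent = c(-10, 10, 35, 55), resolution = 0.5,
                               truth = synthetic_truth(), n_occ = 200L) {
  env <- generate_environment(extent, resolution, length(truth$beta), truth)
  set.seed(truth$seed + 3L)
  g <- env$current[[1]]
  dem_v <- 800 + 600 * random_field(g$nrow, g$ncol, truth$smooth_sigma, 0.3)
  dem_v[dem_v < 0] <- 0
  dem <- raster_grid(dem_v, g$xmin, g$ymax, g$res)
  vec <- generate_rivers_forests_protected(extent, truth)
  occ <- sample_true_occurrences(env$current, truth, n_occ)
  c(list(truth = truth), env,
    list(dem = dem, occurrences = occ), vec)
}
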