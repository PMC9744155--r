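#' Project a fitted ENM over a raster stack
#'
#' Per-cell probability prediction over a named list of predictor rasters
#' (all layers on one shared grid); any nodata in a predictor propagates to
#' the output.
#'
#' @param model an `enm`.
#' @param stack named list of `raster_grid`s covering every model predictor.
#' @return a suitability `raster_grid` with values in \[0, 1\].
#' @export
project_model <- function(model, stack) {
  missing <- setdiff(model$predictor_names, names(stack))
  if (length(missing))
    stop("missing predictor layer(s): ", paste(missing, collapse = ", "))
  stack <- stack[model$predictor_names]
  rg_check_shape(stack)
  g <- stack[[1]]
  X <- sapply(stack, function(s) as.vector(s$values))
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok))
    out[ok] <- stats::predict(model$booster, X[ok, , drop = FALSE])
  raster_grid(matrix(out, g$nrow, g$ncol), g$xmin, g$ymax, g$res)
}

# MESS similarity of a single value against a reference vector.
mess_similarity <- function(p, ref) {
  rmin <- min(ref); rmax <- max(ref); rng <- rmax - rmin
  f <- 100 * mean(ref < p)
  if (rng == 0) {
    if (p == rmin) return(0)
    return(100 * (if (f == 0) p - rmin else rmin - p) / .Machine$double.eps)
  }
  if (f == 0) 100 * (p - rmin) / rng
  else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else 100 * (rmax - p) / rng
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Per cell and predictor, with `f` the percentage of reference values below
#' the cell value: similarity is `100*(p-min)/(max-min)` when `f = 0`, `2f`
#' when `0 < f <= 50`, `2(100-f)` when `50 < f < 100`, and
#' `100*(max-p)/(max-min)` when `f = 100`. The cell's MESS is the minimum
#' similarity across predictors; negative values flag novel (extrapolated)
#' conditions. A zero-variance reference predictor yields similarity 0 where
#' the cell equals the constant and a large negative value otherwise (range
#' replaced by machine epsilon), with a warning.
#'
#' @param reference data.frame of calibration predictor values (the training
#'   table restricted to the model's predictors).
#' @param stack named list of `raster_grid`s matching the reference columns.
#' @return a `raster_grid` of MESS values (nodata propagated).
#' @export
compute_mess <- function(reference, stack) {
  reference <- as.data.frame(reference)
  stopifnot(nrow(reference) > 0)
  missing <- setdiff(names(reference), names(stack))
  if (length(missing))
    stop("missing predictor layer(s): ", paste(missing, collapse = ", "))
  stack <- stack[names(reference)]
  rg_check_shape(stack)
  g <- stack[[1]]
  if (any(vapply(reference, function(r) min(r) == max(r), TRUE)))
    warning("zero-variance reference predictor: MESS range degenerate")
  sims <- vapply(names(reference), function(v) {
    vals <- as.vector(stack[[v]]$values)
    out <- rep(NA_real_, length(vals))
    ok <- !is.na(vals)
    out[ok] <- vapply(vals[ok], mess_similarity, numeric(1),
                      ref = reference[[v]])
    out
  }, numeric(g$nrow * g$ncol))
  sims <- matrix(sims, nrow = g$nrow * g$ncol)
  m <- apply(sims, 1, function(r) if (anyNA(r)) NA_real_ else min(r))
  raster_grid(matrix(m, g$nrow, g$ncol), g$xmin, g$ymax, g$res)
}

#' Similarity-weighted multi-GCM ensemble (MEDI)
#'
#' Combines per-GCM suitability projections of one (scenario, year) into a
#' single surface, weighting each GCM per cell by its clipped MESS
#' similarity: `w_g = max(MESS_g, 0) + 1e-6`, combined suitability
#' `sum(w_g S_g) / sum(w_g)`. A GCM projecting into novel conditions
#' (MESS <= 0) thus contributes at most an epsilon share. Cells where every
#' input is nodata stay nodata.
#'
#' @param maps list of suitability `raster_grid`s, one per GCM.
#' @param mess_maps list of MESS `raster_grid`s, parallel to `maps`.
#' @param eps weight floor (default 1e-6).
#' @return the combined suitability `raster_grid`.
#' @export
combine_medi <- function(maps, mess_maps, eps = 1e-6) {
  stopifnot(length(maps) == length(mess_maps), length(maps) >= 1)
  rg_check_shape(c(maps, mess_maps))
  g <- maps[[1]]
  num <- matrix(0, g$nrow, g$ncol); den <- matrix(0, g$nrow, g$ncol)
  any_ok <- matrix(FALSE, g$nrow, g$ncol)
  for (i in seq_along(maps)) {
    s <- maps[[i]]$values; m <- mess_maps[[i]]$values
    ok <- !is.na(s) & !is.na(m)
    w <- pmax(m, 0) + eps
    num[ok] <- num[ok] + w[ok] * s[ok]
    den[ok] <- den[ok] + w[ok]
    any_ok <- any_ok | ok
  }
  out <- num / den
  out[!any_ok] <- NA_real_
  raster_grid(out, g$xmin, g$ymax, g$res)
}

#' Reclassify suitability to the 1-to-10 scale
#'
#' Equal-interval bins over \[0, 1\]: `v -> min(floor(10 v) + 1, 10)`; a bin
#' edge belongs to the upper bin, so 0.10 maps to class 2 and class 10 is
#' reachable (1.0 -> 10). Nodata is preserved.
#'
#' @param map suitability `raster_grid` with values in \[0, 1\].
#' @return integer-valued `raster_grid` in 1..10.
#' @export
reclassify_suitability <- function(map) {
  v <- map$values
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1)) stop("suitability values outside [0, 1]")
  out <- v
  out[ok] <- pmin(floor(10 * v[ok]) + 1, 10)
  raster_grid(out, map$xmin, map$ymax, map$res)
}
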