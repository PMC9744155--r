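#' SVM separability test between two environmental point sets
#'
#' Two labelled clouds in predictor space overlap unless a hard-margin SVM
#' separates them perfectly. Predictors are z-scored on the pooled set, a
#' two-class SVM with a large misclassification penalty (default 1e6,
#' approximating a hard margin) is fitted, and the verdict is `"non-overlap"`
#' iff training accuracy is 100%. Identical points occurring in both classes
#' make perfect separation impossible, so the verdict is `"overlap"` without
#' fitting.
#'
#' @param a,b matrices/data.frames of predictor values (same columns).
#' @param kernel `"linear"` or `"poly2"` (2nd-degree polynomial,
#'   `(gamma x.x' + 1)^2` with `gamma = 1/n_predictors`).
#' @param cost misclassification penalty (default 1e6).
#' @return list with `verdict` (`"overlap"`/`"non-overlap"`),
#'   `n_support_vectors`, `kernel`.
#' @export
svm_separability <- function(a, b, kernel = c("linear", "poly2"),
                             cost = 1e6) {
  kernel <- match.arg(kernel)
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) > 0, nrow(b) > 0, ncol(a) == ncol(b))
  key <- function(m) apply(round(m, 12), 1, paste, collapse = "|")
  if (length(intersect(key(a), key(b))))
    return(list(verdict = "overlap", n_support_vectors = NA_integer_,
                kernel = kernel))
  x <- rbind(a, b)
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0  # constant column: no information
  y <- factor(rep(c("a", "b"), c(nrow(a), nrow(b))))
  fit <- if (kernel == "linear")
    e1071::svm(x = x, y = y, scale = FALSE, kernel = "linear", cost = cost)
  else
    e1071::svm(x = x, y = y, scale = FALSE, kernel = "polynomial",
               degree = 2, gamma = 1 / ncol(x), coef0 = 1, cost = cost)
  acc <- mean(stats::predict(fit, x) == y)
  list(verdict = if (acc == 1) "non-overlap" else "overlap",
       n_support_vectors = fit$tot.nSV, kernel = kernel)
}

#' Pairwise niche-overlap matrix among point sets
#'
#' Runs [svm_separability()] one-vs-one over all unordered pairs of labelled
#' sets. Sets with fewer than `min_size` points are marked untested (`NA`).
#'
#' @param sets named list of predictor matrices/data.frames.
#' @param kernel passed to [svm_separability()].
#' @param min_size minimum points per set for testing (default 3).
#' @return object of class `overlap_matrix`: `verdicts` (character matrix,
#'   diagonal `"overlap"`), `n_support_vectors` (integer matrix), `kernel`.
#' @export
overlap_matrix <- function(sets, kernel = c("linear", "poly2"),
                           min_size = 3L) {
  kernel <- match.arg(kernel)
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  k <- length(sets); nm <- names(sets)
  verdicts <- matrix(NA_character_, k, k, dimnames = list(nm, nm))
  nsv <- matrix(NA_integer_, k, k, dimnames = list(nm, nm))
  diag(verdicts) <- "overlap"
  ok <- vapply(sets, function(s) NROW(s) >= min_size, TRUE)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!ok[i] || !ok[j]) next
    r <- svm_separability(sets[[i]], sets[[j]], kernel)
    verdicts[i, j] <- verdicts[j, i] <- r$verdict
    nsv[i, j] <- nsv[j, i] <- r$n_support_vectors
  }
  structure(list(verdicts = verdicts, n_support_vectors = nsv,
                 kernel = kernel),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("Niche overlap matrix (%s kernel)\n", x$kernel))
  print(x$verdicts, quote = FALSE)
  invisible(x)
}

#' Protected-area gap analysis
#'
#' For each occurrence: the protection status from point-in-polygon
#' membership (`none`, `natura2000`, `national`, or `both` where the two
#' protection kinds co-occur — via overlapping polygons of both kinds or a
#' polygon of kind `"both"`), and the great-circle distance to the nearest
#' old-growth forest polygon (0 when inside one). Unclosed polygon rings are
#' closed with a warning.
#'
#' @param occ data.frame of occurrences (`lon`, `lat`; a `group` column is
#'   carried into the summary).
#' @param protected list of protected-area polygons (`coords` ring, `kind`
#'   in `natura2000` / `national` / `both`).
#' @param forests list of `forest_polygon` objects.
#' @param densify_step ring densification step (degrees) for boundary
#'   distances.
#' @return list with `records` (per-occurrence data.frame: `protection`,
#'   `distance_to_nearest_forest_km`) and `counts` (table of protection
#'   classes, partitioning the occurrences).
#' @export
gap_analysis <- function(occ, protected, forests, densify_step = 0.02) {
  pts <- cbind(occ$lon, occ$lat)
  ring_of <- function(p) {
    r <- as.matrix(p$coords)
    if (any(r[1, ] != r[nrow(r), ])) {
      warning("unclosed polygon ring closed automatically")
      r <- close_ring(r)
    }
    r
  }
  kinds <- vapply(protected, `[[`, "", "kind")
  in_kind <- function(kind) {
    sel <- protected[kinds == kind]
    if (!length(sel)) return(rep(FALSE, nrow(pts)))
    in_any_polygon(pts, lapply(sel, ring_of))
  }
  in_n2k <- in_kind("natura2000") | in_kind("both")
  in_nat <- in_kind("national") | in_kind("both")
  protection <- ifelse(in_n2k & in_nat, "both",
                ifelse(in_n2k, "natura2000",
                ifelse(in_nat, "national", "none")))
  dist_km <- rep(Inf, nrow(pts))
  for (f in forests) {
    ring <- close_ring(f$ring[, 1:2])
    inside <- mgcv::in.out(ring, pts)
    dense <- densify(ring, densify_step)
    for (i in which(!inside & dist_km > 0)) {
      dist_km[i] <- min(dist_km[i], min(gc_distance_km(pts[i, ], dense)))
    }
    dist_km[inside] <- 0
  }
  records <- data.frame(lon = occ$lon, lat = occ$lat,
                        protection = protection,
                        distance_to_nearest_forest_km = dist_km)
  if (!is.null(occ$group)) records$group <- occ$group
  counts <- table(factor(protection,
                         levels = c("none", "natura2000", "national", "both")))
  list(records = records, counts = counts)
}

#' Sample forest-side environmental point sets
#'
#' Builds, for overlap testing, one predictor-space point per raster cell
#' intersected by each refined forest polygon, labelled by forest category
#' (optionally crossed with a longitude group).
#'
#' @param forests list of `forest_polygon` objects.
#' @param stack named list of predictor `raster_grid`s.
#' @param by_group when TRUE, labels are `category x longitude group` using
#'   [assign_longitude_groups()] defaults on the forest centers.
#' @return named list of predictor matrices (one per label).
#' @export
forest_env_sets <- function(forests, stack, by_group = FALSE) {
  g <- stack[[1]]
  labels <- vapply(forests, function(f) as.character(f$category), "")
  if (by_group) {
    centers <- data.frame(
      lon = vapply(forests, function(f) f$center[["lon"]], 0),
      lat = vapply(forests, function(f) f$center[["lat"]], 0))
    grp <- assign_longitude_groups(centers)$group
    labels <- paste(labels, grp, sep = " | ")
  }
  out <- list()
  for (i in seq_along(forests)) {
    f <- forests[[i]]
    cells <- f$cells
    if (is.null(cells)) {
      xy <- rg_coords(g)
      keep <- gc_distance_km(f$center, xy) <= f$radius_m / 1000
      cells <- arrayInd(which(keep), c(g$nrow, g$ncol))
    }
    if (!NROW(cells)) next
    vals <- sapply(stack, function(s) s$values[cells])
    vals <- matrix(vals, nrow = NROW(cells),
                   dimnames = list(NULL, names(stack)))
    out[[labels[i]]] <- rbind(out[[labels[i]]], vals)
  }
  lapply(out, function(m) m[stats::complete.cases(m), , drop = FALSE])
}
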