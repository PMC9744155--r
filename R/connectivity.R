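#' Build a conductance graph from a suitability raster
#'
#' Each valid (non-nodata) cell becomes a graph node whose conductance is its
#' weighted-suitability value; adjacent nodes are joined by an edge of
#' conductance equal to the mean of the two cell conductances, with diagonal
#' edges (eight-neighborhood) divided by `sqrt(2)` to account for the longer
#' step.
#'
#' @param ws `raster_grid` of weighted suitability (values >= 1 on valid
#'   cells).
#' @param neighborhood `"eight"` (default) or `"four"`.
#' @return object of class `conductance_grid`: `grid`, `neighborhood`,
#'   `node_index` (matrix cell -> node id, NA for nodata), `nodes`
#'   (data.frame `row`, `col`, `lon`, `lat`), `edges` (data.frame `i`, `j`,
#'   `g`).
#' @export
raster_to_graph <- function(ws, neighborhood = c("eight", "four")) {
  neighborhood <- match.arg(neighborhood)
  v <- ws$values
  valid <- !is.na(v)
  if (!any(valid)) stop("all-nodata raster")
  if (any(v[valid] < 0)) stop("negative conductance")
  node_index <- matrix(NA_integer_, ws$nrow, ws$ncol)
  node_index[valid] <- seq_len(sum(valid))
  ij <- arrayInd(which(valid), dim(v))
  xy <- rg_coords(ws)[which(valid), , drop = FALSE]
  nodes <- data.frame(row = ij[, 1], col = ij[, 2],
                      lon = xy[, 1], lat = xy[, 2])
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == "eight")
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (o in offsets) {
    r2 <- ij[, 1] + o[1]; c2 <- ij[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= ws$nrow & c2 >= 1 & c2 <= ws$ncol
    ok[ok] <- !is.na(node_index[cbind(r2[ok], c2[ok])])
    if (!any(ok)) next
    i <- node_index[ij[ok, , drop = FALSE]]
    j <- node_index[cbind(r2[ok], c2[ok])]
    g <- (v[ij[ok, , drop = FALSE]] + v[cbind(r2[ok], c2[ok])]) / 2
    if (sum(abs(o)) == 2L) g <- g / sqrt(2)
    edges[[length(edges) + 1L]] <- data.frame(i = i, j = j, g = g)
  }
  edges <- do.call(rbind, edges)
  structure(list(grid = ws, neighborhood = neighborhood,
                 node_index = node_index, nodes = nodes, edges = edges),
            class = "conductance_grid")
}

# Sparse graph Laplacian of a conductance_grid.
graph_laplacian <- function(cg) {
  n <- nrow(cg$nodes)
  e <- cg$edges
  A <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = c(e$g, e$g), dims = c(n, n))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

# Connected component id per node (BFS over the edge list).
graph_components <- function(cg) {
  n <- nrow(cg$nodes)
  adj <- split(c(cg$edges$j, cg$edges$i), c(cg$edges$i, cg$edges$j))
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[as.character(u)]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# Snap focal lon/lat points to node ids; merges coincident cells (warning).
snap_focal_nodes <- function(cg, points) {
  rc <- rg_cell(cg$grid, points$lon, points$lat)
  if (anyNA(rc)) stop("focal point outside the raster extent")
  ids <- cg$node_index[rc]
  if (anyNA(ids)) stop("focal point on a nodata cell")
  if (anyDuplicated(ids)) {
    warning("coincident focal cells merged")
    ids <- unique(ids)
  }
  ids
}

# Per-cell current magnitude raster from node potentials: half the sum of
# absolute currents of the incident edges plus the node's |net injection|
# (L v), so pass-through cells report their throughflow and terminal cells
# their full injected/absorbed current.
cell_current_map <- function(cg, potential, laplacian = graph_laplacian(cg)) {
  e <- cg$edges
  I_e <- e$g * abs(potential[e$i] - potential[e$j])
  node_cur <- numeric(nrow(cg$nodes))
  agg <- rowsum(c(I_e, I_e), c(e$i, e$j))
  node_cur[as.integer(rownames(agg))] <- agg[, 1]
  inj <- as.vector(laplacian %*% potential)
  node_cur <- (node_cur + abs(inj)) / 2
  out <- matrix(NA_real_, cg$grid$nrow, cg$grid$ncol)
  out[cbind(cg$nodes$row, cg$nodes$col)] <- node_cur
  raster_grid(out, cg$grid$xmin, cg$grid$ymax, cg$grid$res)
}

#' Pairwise circuit-theory connectivity among focal points
#'
#' For every unordered pair of focal nodes, injects a unit current at one
#' node, grounds the other, and solves the graph Laplacian system. The
#' effective resistance is the potential difference between the pair; the
#' cumulative current map sums the per-cell current magnitudes over all
#' pairs. Pairs in disconnected components get infinite resistance and zero
#' current, with a warning.
#'
#' @param cg a [raster_to_graph()] result.
#' @param focal data.frame of focal points (`lon`, `lat`), >= 2; each snaps
#'   to its containing cell.
#' @return object of class `pairwise_circuit`: `resistances` (symmetric
#'   matrix), `cumulative_current` (`raster_grid`), `focal_nodes`.
#' @export
solve_pairwise <- function(cg, focal) {
  ids <- snap_focal_nodes(cg, focal)
  if (length(ids) < 2) stop("need at least 2 distinct focal nodes")
  n <- nrow(cg$nodes)
  L <- graph_laplacian(cg)
  comp <- graph_components(cg)
  m <- length(ids)
  R <- matrix(0, m, m)
  cum <- matrix(0, cg$grid$nrow, cg$grid$ncol)
  warned <- FALSE
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    s <- ids[a]; t <- ids[b]
    if (comp[s] != comp[t]) {
      if (!warned) warning("focal nodes in disconnected components: infinite resistance")
      warned <- TRUE
      R[a, b] <- R[b, a] <- Inf
      next
    }
    keep <- setdiff(seq_len(n), t)
    rhs <- numeric(n - 1)
    rhs[match(s, keep)] <- 1
    vkeep <- Matrix::solve(L[keep, keep, drop = FALSE], rhs)
    potential <- numeric(n)
    potential[keep] <- as.vector(vkeep)
    R[a, b] <- R[b, a] <- potential[s]
    cur <- cell_current_map(cg, potential, L)$values
    cum <- cum + ifelse(is.na(cur), 0, cur)
  }
  cum[is.na(cg$grid$values)] <- NA
  structure(list(resistances = R,
                 cumulative_current = raster_grid(cum, cg$grid$xmin,
                                                  cg$grid$ymax, cg$grid$res),
                 focal_nodes = ids),
            class = "pairwise_circuit")
}

#' Advanced (multi-source, grounded-area) circuit solve
#'
#' All cells inside the ground polygons are tied to zero potential
#' (infinite-conductance ground); the stated currents are injected at the
#' source points and a single linear system is solved. Sources falling inside
#' a ground polygon are ignored with a warning.
#'
#' @param cg a [raster_to_graph()] result.
#' @param sources data.frame with `lon`, `lat` and optionally `amps`
#'   (default 1 each).
#' @param grounds list of ground polygons (`coords` ring matrices, or
#'   `forest_polygon` objects whose `ring` is used).
#' @return object of class `current_map`: `grid` (`raster_grid` of per-cell
#'   current magnitude), `mode = "advanced"`, `source_nodes`, `ground_nodes`.
#' @export
solve_advanced <- function(cg, sources, grounds) {
  rings <- lapply(grounds, function(g)
    if (inherits(g, "forest_polygon")) g$ring[, 1:2] else g$coords)
  pts <- cbind(cg$nodes$lon, cg$nodes$lat)
  grounded <- in_any_polygon(pts, rings)
  # a polygon smaller than a cell may contain no cell center: ground the
  # cells its vertices fall in instead
  for (r in rings) {
    rc <- rg_cell(cg$grid, r[, 1], r[, 2])
    rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
    ids <- cg$node_index[rc]
    grounded[ids[!is.na(ids)]] <- TRUE
  }
  if (!any(grounded)) stop("no ground cells inside the raster")
  amps <- if (!is.null(sources$amps)) sources$amps else rep(1, NROW(sources))
  rc <- rg_cell(cg$grid, sources$lon, sources$lat)
  if (anyNA(rc)) stop("source point outside the raster extent")
  ids_all <- cg$node_index[rc]
  if (anyNA(ids_all)) stop("source point on a nodata cell")
  if (anyDuplicated(ids_all)) warning("coincident source cells merged")
  amps <- as.vector(rowsum(amps, ids_all))  # sum injections per cell
  ids <- sort(unique(ids_all))
  drop <- grounded[ids]
  if (any(drop)) {
    warning("source(s) inside a ground polygon ignored")
    ids <- ids[!drop]; amps <- amps[!drop]
  }
  if (length(ids) == 0) stop("no usable source nodes")
  n <- nrow(cg$nodes)
  L <- graph_laplacian(cg)
  keep <- which(!grounded)
  rhs <- numeric(n)
  rhs[ids] <- amps
  potential <- numeric(n)
  potential[keep] <- as.vector(Matrix::solve(L[keep, keep, drop = FALSE],
                                             rhs[keep]))
  structure(list(grid = cell_current_map(cg, potential, L),
                 potential = potential, mode = "advanced",
                 source_nodes = ids, ground_nodes = which(grounded)),
            class = "current_map")
}

#' Standardized connectivity change index (SCCI)
#'
#' Cellwise `(F - C) / (F + C)` between a future and a current current map,
#' in \[-1, 1\]: -1 where connectivity is lost entirely, +1 where it is
#' entirely gained, 0 where it is stable (including cells with no current in
#' either scenario).
#'
#' @param current_now,current_future `raster_grid`s of per-cell current (or
#'   `pairwise_circuit` / `current_map` objects, whose maps are taken).
#' @return `raster_grid` with values in \[-1, 1\].
#' @export
compute_scci <- function(current_now, current_future) {
  as_grid <- function(x) {
    if (inherits(x, "pairwise_circuit")) return(x$cumulative_current)
    if (inherits(x, "current_map")) return(x$grid)
    x
  }
  C <- as_grid(current_now); F_ <- as_grid(current_future)
  rg_check_shape(C, F_)
  cv <- C$values; fv <- F_$values
  if (any(cv < 0, na.rm = TRUE) || any(fv < 0, na.rm = TRUE))
    stop("negative currents")
  s <- (fv - cv) / (fv + cv)
  s[!is.na(cv) & cv == 0 & fv == 0] <- 0
  raster_grid(s, C$xmin, C$ymax, C$res)
}

#' Classify old-growth forests as reachable or remote
#'
#' A forest is reachable when the minimum great-circle distance from its
#' polygon to any occurrence is at most `radius_km` (default 130 km, the
#' species' maximum recorded daily foraging transit).
#'
#' @param forests list of `forest_polygon` objects.
#' @param occ data.frame of occurrences (`lon`, `lat`).
#' @param radius_km buffer radius in km (> 0; default 130).
#' @return character vector, `"reachable"` or `"remote"` per forest, with
#'   attribute `min_dist_km`.
#' @export
classify_reachable_forests <- function(forests, occ, radius_km = 130) {
  stopifnot(radius_km > 0, NROW(occ) >= 1)
  opts <- cbind(occ$lon, occ$lat)
  dmin <- vapply(forests, function(f) {
    ring <- f$ring
    inside <- mgcv::in.out(close_ring(ring[, 1:2]), opts)
    if (any(inside)) return(0)
    min(vapply(seq_len(nrow(opts)), function(i)
      min(gc_distance_km(opts[i, ], ring[, 1:2])), numeric(1)))
  }, numeric(1))
  out <- ifelse(dmin <= radius_km, "reachable", "remote")
  attr(out, "min_dist_km") <- dmin
  out
}
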