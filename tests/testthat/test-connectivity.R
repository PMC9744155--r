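test_that("graph construction matches the stated edge rules", {
  # 1x3 uniform grid: two unit edges
  cg <- raster_to_graph(uniform_ws(1, 3), "four")
  expect_equal(nrow(cg$edges), 2)
  expect_equal(cg$edges$g, c(1, 1))
  # eight-neighborhood diagonal between conductance-2 cells: 2/sqrt(2)
  cg2 <- raster_to_graph(uniform_ws(2, 2, value = 2), "eight")
  diag_edges <- cg2$edges$g[abs(cg2$nodes$row[cg2$edges$i] -
                                  cg2$nodes$row[cg2$edges$j]) == 1 &
                              abs(cg2$nodes$col[cg2$edges$i] -
                                    cg2$nodes$col[cg2$edges$j]) == 1]
  expect_equal(diag_edges, rep(2 / sqrt(2), 2))
  # edge count equals the brute-force count of valid adjacent pairs
  set.seed(13)
  v <- matrix(sample(1:10, 42, TRUE), 6, 7)
  v[sample(42, 6)] <- NA
  g <- raster_grid(v, 0, 6, 1)
  for (nb in c("four", "eight")) {
    cg3 <- raster_to_graph(g, nb)
    count <- 0L
    offs <- if (nb == "four") list(c(0, 1), c(1, 0))
            else list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
    for (r in 1:6) for (cc in 1:7) for (o in offs) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 >= 1 && r2 <= 6 && c2 >= 1 && c2 <= 7 &&
          !is.na(v[r, cc]) && !is.na(v[r2, c2])) count <- count + 1L
    }
    expect_equal(nrow(cg3$edges), count)
  }
  expect_error(raster_to_graph(raster_grid(matrix(NA_real_, 2, 2), 0, 2, 1)),
               "nodata")
})

test_that("series and parallel networks give their closed-form resistances", {
  g1 <- uniform_ws(1, 3)
  pw1 <- solve_pairwise(raster_to_graph(g1, "four"),
                        cell_points(g1, c(1, 1), c(1, 3)))
  expect_equal(pw1$resistances[1, 2], 2, tolerance = 1e-12)
  # 2x2 square, opposite corners: two parallel 2-resistor paths -> R = 1
  g2 <- uniform_ws(2, 2)
  pw2 <- solve_pairwise(raster_to_graph(g2, "four"),
                        cell_points(g2, c(1, 2), c(1, 2)))
  expect_equal(pw2$resistances[1, 2], 1, tolerance = 1e-12)
})

test_that("effective resistance is a metric and obeys Rayleigh monotonicity", {
  set.seed(17)
  v <- matrix(sample(1:10, 25, TRUE), 5, 5)
  g <- raster_grid(v, 0, 5, 1)
  cg <- raster_to_graph(g)
  foc <- cell_points(g, c(1, 3, 5), c(1, 4, 2))
  R <- solve_pairwise(cg, foc)$resistances
  expect_equal(R, t(R))
  expect_true(all(diag(R) == 0))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_lte(R[i, j], R[i, k] + R[k, j] + 1e-10)
  # raising one cell's conductance never raises any resistance
  v2 <- v; v2[3, 3] <- v2[3, 3] + 5
  R2 <- solve_pairwise(raster_to_graph(raster_grid(v2, 0, 5, 1)),
                       foc)$resistances
  expect_true(all(R2 <= R + 1e-10))
})

test_that("disconnected focal pairs report infinite resistance", {
  v <- matrix(1, 3, 3); v[, 2] <- NA  # two separated columns
  g <- raster_grid(v, 0, 3, 1)
  cg <- raster_to_graph(g, "four")
  expect_warning(pw <- solve_pairwise(cg, cell_points(g, c(2, 2), c(1, 3))),
                 "disconnected")
  expect_true(is.infinite(pw$resistances[1, 2]))
})

test_that("advanced mode conserves current and matches pairwise for one pair", {
  set.seed(19)
  v <- matrix(sample(1:10, 100, TRUE), 10, 10)
  g <- raster_grid(v, 0, 10, 1)
  cg <- raster_to_graph(g)
  # one-cell ground polygon around cell (8, 8)
  gc <- cell_points(g, 8, 8)
  ring <- cbind(gc$lon + 0.4 * c(-1, 1, 1, -1, -1),
                gc$lat + 0.4 * c(-1, -1, 1, 1, -1))
  src <- cell_points(g, 2, 3)
  adv <- solve_advanced(cg, src, list(list(coords = ring)))
  pw <- solve_pairwise(cg, rbind(src, gc))
  expect_equal(adv$grid$values, pw$cumulative_current$values,
               tolerance = 1e-8)
  # Kirchhoff: two unit sources, total current at grounds = 2
  src2 <- cell_points(g, c(2, 5), c(3, 1))
  adv2 <- solve_advanced(cg, src2, list(list(coords = ring)))
  gn <- adv2$ground_nodes
  inflow <- sum(adv2$grid$values[cbind(cg$nodes$row[gn], cg$nodes$col[gn])])
  expect_equal(inflow, 2, tolerance = 1e-8)
  # superposition on the linear network
  a1 <- solve_advanced(cg, src2[1, ], list(list(coords = ring)))
  a2 <- solve_advanced(cg, src2[2, ], list(list(coords = ring)))
  sup <- a1$potential + a2$potential
  expect_equal(adv2$potential, sup, tolerance = 1e-8)
  # a source inside the ground polygon is ignored with a warning
  expect_warning(solve_advanced(cg, rbind(src, gc), list(list(coords = ring))),
                 "ignored")
})

test_that("SCCI hits its endpoints and is antisymmetric", {
  mk <- function(v) raster_grid(matrix(v, 2, 3), 0, 2, 1)
  C <- mk(c(0, 1, 2, 0, 5, 3)); F_ <- mk(c(0, 0, 2, 4, 1, 3))
  s <- compute_scci(C, F_)
  expect_equal(s$values[1, 1], 0)    # 0/0 -> stability
  expect_equal(s$values[2, 1], -1)   # C>0, F=0
  expect_equal(s$values[2, 2], 1)    # C=0, F>0
  expect_true(all(s$values >= -1 & s$values <= 1))
  expect_equal(compute_scci(C, C)$values, matrix(0, 2, 3))
  s_rev <- compute_scci(F_, C)
  expect_equal(s$values, -s_rev$values, tolerance = 1e-12)
  expect_error(compute_scci(mk(-1), mk(1)), "negative")
})

test_that("refining a uniform strip leaves per-gap resistance unchanged", {
  coarse <- uniform_ws(1, 10, value = 4)
  fine <- raster_grid(matrix(4, 1, 20), 0, 1, 0.5)
  Rc <- solve_pairwise(raster_to_graph(coarse, "four"),
                       cell_points(coarse, c(1, 1), c(1, 10)))$resistances[1, 2]
  Rf <- solve_pairwise(raster_to_graph(fine, "four"),
                       cell_points(fine, c(1, 1), c(1, 20)))$resistances[1, 2]
  expect_lt(abs(Rc / 9 - Rf / 19) / (Rc / 9), 0.05)
})

test_that("forests are classified reachable within the buffer radius", {
  occ <- data.frame(lon = 0, lat = 45)
  # ~1 deg latitude = 111.195 km; place forests by latitude offset
  at_km <- function(km) geosphere::destPoint(c(0, 45), 0, km * 1000,
                                             r = 6371008.8)
  near <- at_km(120); far <- at_km(131 + 0.06)  # +60 m for the tiny radius
  f_near <- forest_point_to_polygon(near[1], near[2], 1)   # radius ~56 m
  f_far <- forest_point_to_polygon(far[1], far[2], 1)
  cls <- classify_reachable_forests(list(f_near, f_far), occ)
  expect_equal(as.vector(cls), c("reachable", "remote"))
  # brute-force check of the stored minimum distances
  d <- attr(cls, "min_dist_km")
  brute <- vapply(list(f_near, f_far), function(f)
    min(gc_distance_km(c(0, 45), f$ring[, 1:2])), numeric(1))
  expect_equal(d, brute, tolerance = 1e-9)
})
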