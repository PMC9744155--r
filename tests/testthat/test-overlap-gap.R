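test_that("distant clusters separate and identical clouds overlap", {
  set.seed(22)
  a <- matrix(rnorm(60), ncol = 2) + 10   # 10 sd apart
  b <- matrix(rnorm(60), ncol = 2) - 10
  r <- svm_separability(a, b, "linear")
  expect_equal(r$verdict, "non-overlap")
  expect_gt(r$n_support_vectors, 0)
  same <- svm_separability(a, a, "linear")
  expect_equal(same$verdict, "overlap")
  expect_true(is.na(same$n_support_vectors))  # no fit attempted
})

test_that("a ring around a disk needs the quadratic kernel to separate", {
  s <- ring_disk_sets()
  # no hyperplane can separate: the disk's points lie inside the ring's hull
  expect_equal(svm_separability(s$ring, s$disk, "linear")$verdict, "overlap")
  expect_equal(svm_separability(s$ring, s$disk, "poly2")$verdict,
               "non-overlap")
})

test_that("verdicts are invariant to affine predictor rescaling", {
  s <- ring_disk_sets(seed = 29)
  rescale <- function(m) cbind(5 * m[, 1] - 2, -0.3 * m[, 2] + 7)
  for (k in c("linear", "poly2")) {
    expect_equal(svm_separability(s$ring, s$disk, k)$verdict,
                 svm_separability(rescale(s$ring), rescale(s$disk), k)$verdict)
  }
})

test_that("separability survives set shrinkage", {
  set.seed(24)
  a <- matrix(rnorm(80), ncol = 2) + 6
  b <- matrix(rnorm(80), ncol = 2) - 6
  expect_equal(svm_separability(a, b, "linear")$verdict, "non-overlap")
  for (rep in 1:5) {
    sa <- a[sample(40, 12), ]; sb <- b[sample(40, 12), ]
    expect_equal(svm_separability(sa, sb, "linear")$verdict, "non-overlap")
  }
})

test_that("the overlap matrix is symmetric with an overlap diagonal", {
  set.seed(25)
  west <- matrix(rnorm(40, sd = 0.7), ncol = 2) - 5
  east <- matrix(rnorm(40, sd = 0.7), ncol = 2) + 5
  central <- rbind(west[1:8, ] + 0.2, east[1:8, ] - 0.2)
  om <- overlap_matrix(list(West = west, Central = central, East = east),
                       "linear")
  expect_equal(om$verdicts, t(om$verdicts))
  expect_true(all(diag(om$verdicts) == "overlap"))
  # the constructed geography: West-East separate, Central straddles both
  expect_equal(om$verdicts["West", "East"], "non-overlap")
  expect_equal(om$verdicts["West", "Central"], "overlap")
  expect_equal(om$verdicts["East", "Central"], "overlap")
  # undersized sets are left untested
  om2 <- overlap_matrix(list(A = west, B = east[1:2, ]), "linear")
  expect_true(is.na(om2$verdicts["A", "B"]))
})

test_that("gap analysis assigns protection classes that partition the records", {
  sq <- function(cx, cy, half) cbind(cx + half * c(-1, 1, 1, -1, -1),
                                     cy + half * c(-1, -1, 1, 1, -1))
  protected <- list(
    list(coords = sq(0, 0, 1), kind = "national"),
    list(coords = sq(5, 0, 1), kind = "natura2000"),
    list(coords = sq(0.9, 0.9, 0.5), kind = "natura2000"),  # overlaps national
    list(coords = sq(10, 0, 1), kind = "both"))
  occ <- data.frame(lon = c(0, 5, 0.95, 10, 20), lat = c(0, 0, 0.95, 0, 0))
  forest <- forest_point_to_polygon(0, 3, 100)
  ga <- gap_analysis(occ, protected, list(forest))
  expect_equal(ga$records$protection,
               c("national", "natura2000", "both", "both", "none"))
  expect_equal(sum(ga$counts), nrow(occ))
  # distance: occurrence at (0,0) is ~3 deg south of the forest center
  d <- ga$records$distance_to_nearest_forest_km[1]
  direct <- gc_distance_km(c(0, 0), c(0, 3)) - forest$radius_m / 1000
  expect_equal(d, direct, tolerance = 0.001)
})

test_that("forest distances match a densified brute-force scan within 0.1 km", {
  set.seed(26)
  forests <- lapply(1:3, function(i)
    forest_point_to_polygon(runif(1, -2, 2), runif(1, 43, 47),
                            10^runif(1, 1, 3.5)))
  occ <- data.frame(lon = runif(6, -2, 2), lat = runif(6, 43, 47))
  ga <- gap_analysis(occ, list(), forests)
  for (i in seq_len(nrow(occ))) {
    brute <- min(vapply(forests, function(f) {
      ring <- nichescape:::densify(nichescape:::close_ring(f$ring[, 1:2]), 0.002)
      inside <- mgcv::in.out(nichescape:::close_ring(f$ring[, 1:2]),
                             cbind(occ$lon[i], occ$lat[i]))
      if (inside) 0 else min(gc_distance_km(c(occ$lon[i], occ$lat[i]), ring))
    }, numeric(1)))
    expect_lt(abs(ga$records$distance_to_nearest_forest_km[i] - brute), 0.1)
  }
})

test_that("occurrence inside a lone national polygon is classed national", {
  poly <- list(list(coords = cbind(c(0, 2, 2, 0, 0), c(0, 0, 2, 2, 0)),
                    kind = "national"))
  ga <- gap_analysis(data.frame(lon = 1, lat = 1), poly, list())
  expect_equal(ga$records$protection, "national")
  expect_true(is.infinite(ga$records$distance_to_nearest_forest_km))
})

test_that("forest-side environmental point sets are labelled and complete", {
  ls <- small_landscape()
  # areas large enough that the disks cover several cells of the 0.5-deg grid
  forests <- list(
    forest_point_to_polygon(-5, 45, 8e5, category = "Old-Growth Forest"),
    forest_point_to_polygon(3, 50, 1.5e6, category = "Long Untouched Forest"),
    forest_point_to_polygon(0, 40, 8e5, category = "Old-Growth Forest"))
  sets <- forest_env_sets(forests, ls$current)
  expect_setequal(names(sets),
                  c("Old-Growth Forest", "Long Untouched Forest"))
  for (s in sets) {
    expect_gt(nrow(s), 0)
    expect_equal(colnames(s), names(ls$current))
    expect_false(anyNA(s))
  }
})
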