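# Small reusable fitted model: logistic truth on three predictors.
fit_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(101)
    n <- 500
    X <- data.frame(P1 = rnorm(n), P2 = rnorm(n), P3 = rnorm(n))
    y <- rbinom(n, 1, plogis(2 * X$P1 - 1 * X$P2))
    tab <- cbind(X, label = y, lon = runif(n, 0, 10), lat = runif(n, 40, 50))
    tab <- assign_case_weights(tab)
    grid <- enm_tuning_grid(shrinkage = 0.1, interaction_depth = 2,
                            min_obs_in_node = 5, bag_fraction = 0.8,
                            n_trees_max = 120, cv_folds = 3)
    cache <<- fit_enm(tab, grid, seed = 1)
    cache
  }
})

test_that("VIF selection keeps orthogonal predictors and drops collinear ones", {
  set.seed(7)
  X <- data.frame(a = rnorm(1000), b = rnorm(1000))
  out <- vif_select(X)
  expect_equal(sort(out$retained), c("a", "b"))
  expect_equal(nrow(out$trace), 0)
  # near-exact linear combination: brute-force VIF via OLS R^2 confirms > 10
  X$c <- X$a + X$b + rnorm(1000, sd = 0.01)
  r2 <- summary(lm(c ~ a + b, data = X))$r.squared
  expect_gt(1 / (1 - r2), 10)
  out2 <- vif_select(X)
  expect_equal(length(out2$retained), 2)
  expect_equal(nrow(out2$trace), 1)
  # the >= rule: a predictor sitting exactly at the threshold is removed
  vifs <- vapply(seq_along(X), function(j)
    1 / (1 - summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared), numeric(1))
  out3 <- vif_select(X, threshold = max(vifs))
  expect_equal(nrow(out3$trace), 1)
})

test_that("perfect collinearity is removed first with infinite VIF", {
  set.seed(8)
  X <- data.frame(a = rnorm(100), b = rnorm(100))
  X$c <- X$a + X$b
  out <- vif_select(X)
  expect_true(is.infinite(out$trace$vif[1]))
  expect_equal(length(out$retained), 2)
})

test_that("disk pseudo-absences respect the annulus and match the exhaustive scan", {
  dom <- raster_grid(matrix(0, 40, 40), 0, 20, 0.5)
  occ <- data.frame(lon = c(5, 14), lat = c(10, 6))
  pa <- suppressWarnings(
    sample_disk_pseudoabsences(occ, dom, n = 10000, r_min_km = 130,
                               r_max_km = 250, seed = 3))
  nearest <- function(lon, lat) {
    min(gc_distance_km(c(lon, lat), cbind(occ$lon, occ$lat)))
  }
  d <- mapply(nearest, pa$lon, pa$lat)
  expect_true(all(d >= 130 & d <= 250))
  # brute-force eligible-cell count over every cell
  xy <- rg_coords(dom)
  dall <- pmin(gc_distance_km(c(occ$lon[1], occ$lat[1]), xy),
               gc_distance_km(c(occ$lon[2], occ$lat[2]), xy))
  expect_equal(attr(pa, "n_eligible"), sum(dall >= 130 & dall <= 250))
  # a candidate below r_min is never sampled
  one <- data.frame(lon = 5, lat = 10)
  pa1 <- suppressWarnings(
    sample_disk_pseudoabsences(one, dom, n = 1e5, r_min_km = 130,
                               r_max_km = 250, seed = 1))
  d1 <- gc_distance_km(c(5, 10), cbind(pa1$lon, pa1$lat))
  expect_gte(min(d1), 130)
})

test_that("case weights equalize the class totals", {
  tab <- data.frame(label = c(rep(1, 10), rep(0, 40)))
  out <- assign_case_weights(tab)
  expect_equal(unique(out$weight[out$label == 1]), 4)
  expect_equal(sum(out$weight[out$label == 1]),
               sum(out$weight[out$label == 0]))
  eq <- assign_case_weights(data.frame(label = rep(c(1, 0), 5)))
  expect_true(all(eq$weight == 1))
  big <- assign_case_weights(data.frame(label = rep(c(1, 0), c(260, 5000))))
  expect_equal(unique(big$weight[big$label == 1]), 5000 / 260)
  expect_error(assign_case_weights(data.frame(label = rep(0, 5))), "presence")
})

test_that("a single-combination grid is returned as fitted and refits reproducibly", {
  m <- fit_fixture()
  expect_s3_class(m, "enm")
  expect_equal(nrow(m$cv_table), 1)
  expect_equal(m$best_params$shrinkage, 0.1)
  expect_equal(m$cv_rmse, m$cv_table$cv_rmse[1])
  # determinism of the tuning path under a fixed seed
  cv2 <- enm_cv_grid(m$table, m$grid, seed = 1)
  expect_equal(cv2$cv_rmse, m$cv_table$cv_rmse)
  expect_output(print(m), "Boosted-tree")
})

test_that("reweighted duplication of pseudo-absences keeps the grid ranking", {
  set.seed(21)
  n <- 150
  X <- data.frame(P1 = rnorm(n), P2 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * X$P1))
  tab <- assign_case_weights(cbind(X, label = y))
  abs_rows <- tab[tab$label == 0, ]
  tab2 <- assign_case_weights(rbind(tab, abs_rows)[c("P1", "P2", "label")])
  grid <- enm_tuning_grid(shrinkage = c(0.05, 0.3), interaction_depth = 1,
                          min_obs_in_node = 5, bag_fraction = 1,
                          n_trees_max = 60, cv_folds = 3)
  r1 <- enm_cv_grid(tab, grid, seed = 5)
  r2 <- enm_cv_grid(tab2, grid, seed = 5)
  expect_equal(order(r1$cv_rmse), order(r2$cv_rmse))
})

test_that("Boyce index tracks sampling design and degrades with noise", {
  set.seed(31)
  bg <- runif(4000)
  pres <- sample(bg, 1200, replace = TRUE, prob = bg)
  expect_gt(evaluate_boyce(pres, bg), 0.9)
  pres_inv <- sample(bg, 1200, replace = TRUE, prob = 1 - bg)
  expect_lt(evaluate_boyce(pres_inv, bg), -0.9)
  # true suitability scores higher than a noise-degraded copy
  noisy_pres <- pmin(pmax(pres + rnorm(1200, sd = 0.4), 0), 1)
  noisy_bg <- pmin(pmax(bg + rnorm(4000, sd = 0.4), 0), 1)
  expect_gt(evaluate_boyce(pres, bg), evaluate_boyce(noisy_pres, noisy_bg))
  expect_error(evaluate_boyce(rep(0.5, 10), rep(0.5, 100)), "constant")
})

test_that("correlogram Moran's I matches the hand formula on one class", {
  # 5 points close enough that a single class holds every pair
  pts <- data.frame(lon = c(0, 0.1, 0.2, 0.05, 0.15),
                    lat = c(0, 0.05, 0.1, 0.15, 0.02))
  z <- c(1.2, -0.5, 0.3, 0.8, -1.1)
  z10 <- rep(z, 2)[1:10]  # pad to meet the >= 10 points contract
  pts10 <- rbind(pts, pts + 0.001)
  out <- residual_correlogram(z10, pts10, n_classes = 1, n_perm = 199)
  W <- 1 - diag(10)
  expect_equal(out$moran_i[1], moran_oracle(z10, W), tolerance = 1e-12)
  expect_equal(out$n_pairs[1], 45)
})

test_that("correlogram flags constructed autocorrelation but not white noise", {
  set.seed(12)
  pts <- data.frame(lon = runif(40, 0, 5), lat = runif(40, 40, 45))
  smooth <- sin(pts$lon) + cos(pts$lat)      # smooth spatial field
  out_s <- residual_correlogram(smooth, pts, n_classes = 5, n_perm = 199)
  expect_gt(out_s$moran_i[1], 0)
  expect_lt(out_s$p_value[1], 0.05)
  frac_ns <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    iid <- rnorm(40)
    out <- residual_correlogram(iid, pts, n_classes = 5, n_perm = 199,
                                seed = s)
    frac_ns[s] <- mean(out$p_value > 0.05, na.rm = TRUE)
  }
  expect_gt(mean(frac_ns), 0.85)
})

test_that("variable contributions sum to 100 and find the dominant signal", {
  m <- fit_fixture()
  contr <- variable_contributions(m)
  expect_equal(sum(contr), 100, tolerance = 0.01)
  expect_equal(names(which.max(contr)), "P1")
  perm <- variable_contributions(m, method = "permutation", seed = 2)
  expect_equal(sum(perm), 100, tolerance = 0.01)
  expect_equal(names(which.max(perm)), "P1")
  # single-predictor model: trivially 100%
  tab1 <- m$table[c("P1", "label", "weight")]
  g1 <- enm_tuning_grid(shrinkage = 0.1, interaction_depth = 1,
                        min_obs_in_node = 5, bag_fraction = 1,
                        n_trees_max = 30, cv_folds = 2)
  m1 <- fit_enm(tab1, g1, seed = 1)
  expect_equal(unname(variable_contributions(m1)), 100)
})

test_that("Friedman's H separates additive from multiplicative truths", {
  set.seed(41)
  n <- 400
  X <- data.frame(P1 = rnorm(n), P2 = rnorm(n))
  grid <- enm_tuning_grid(shrinkage = 0.1, interaction_depth = 3,
                          min_obs_in_node = 5, bag_fraction = 1,
                          n_trees_max = 80, cv_folds = 2)
  y_add <- rbinom(n, 1, plogis(X$P1 + X$P2))
  m_add <- fit_enm(assign_case_weights(cbind(X, label = y_add)), grid, seed = 1)
  y_mul <- rbinom(n, 1, plogis(3 * X$P1 * X$P2))
  m_mul <- fit_enm(assign_case_weights(cbind(X, label = y_mul)), grid, seed = 1)
  h_add <- interaction_strength(m_add, c("P1", "P2"), grid_points = 20)
  h_mul <- interaction_strength(m_mul, c("P1", "P2"), grid_points = 20)
  expect_gte(h_add, 0)
  expect_gt(h_mul, h_add)
})

test_that("marginal response curves follow the truth and stay in range", {
  m <- fit_fixture()
  mr <- marginal_response(m, "P1")
  expect_gt(cor(mr$value, mr$prediction, method = "spearman"), 0.9)
  expect_gte(min(mr$value), min(m$table$P1))
  expect_lte(max(mr$value), max(m$table$P1))
  # flat predictor: curve range is a small share of the prediction range
  mr3 <- marginal_response(m, "P3")
  pred_range <- diff(range(predict(m)))
  expect_lt(diff(range(mr3$prediction)), 0.25 * pred_range)
})

test_that("non-finite predictors are rejected before fitting", {
  tab <- data.frame(P1 = c(1, Inf, 3, 4), label = c(1, 0, 1, 0),
                    weight = 1)
  g <- enm_tuning_grid(shrinkage = 0.1, interaction_depth = 1,
                       min_obs_in_node = 1, bag_fraction = 1,
                       n_trees_max = 5, cv_folds = 2)
  expect_error(fit_enm(tab, g), "non-finite")
})
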