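#' Iterative variance-inflation-factor predictor selection
#'
#' Repeatedly drops the predictor with the largest VIF while that VIF is at
#' or above `threshold` (>= rule). `VIF_j = 1/(1 - R^2_j)` where `R^2_j` is
#' from the OLS regression of predictor `j` on all remaining predictors.
#' A perfectly collinear predictor is removed first with an infinite VIF.
#'
#' @param table data.frame or matrix of candidate predictors (rows > columns).
#' @param threshold exclusion threshold (default 10).
#' @return list with `retained` (names kept) and `trace` (data.frame of the
#'   removal steps: `step`, `removed`, `vif`).
#' @export
vif_select <- function(table, threshold = 10) {
  X <- as.data.frame(table)
  stopifnot(ncol(X) >= 2, nrow(X) > ncol(X))
  trace <- data.frame(step = integer(), removed = character(),
                      vif = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (ncol(X) < 2) break
    vifs <- vapply(seq_len(ncol(X)), function(j) {
      # perfect fits are legitimate input here (exact collinearity -> Inf)
      r2 <- suppressWarnings(
        summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    worst <- which.max(vifs)
    if (vifs[worst] < threshold) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = names(X)[worst],
                                     vif = vifs[worst]))
    X <- X[-worst]
  }
  list(retained = names(X), trace = trace)
}

#' Disk pseudo-absence sampling
#'
#' Samples background points uniformly among the non-nodata cells of `domain`
#' whose great-circle distance to the NEAREST presence lies in
#' `[r_min_km, r_max_km]` — an annulus that keeps pseudo-absences outside the
#' species' daily movement range but close enough for informative contrast.
#' `r_min_km = 0` with a large `r_max_km` degenerates to plain background
#' sampling.
#'
#' @param occ data.frame of presences (`lon`, `lat`).
#' @param domain `raster_grid` defining the candidate cells.
#' @param n number of pseudo-absences requested (default 5000).
#' @param r_min_km,r_max_km annulus radii in km (defaults 130 and 250).
#' @param seed RNG seed.
#' @return data.frame `lon`, `lat` of sampled cell centers, with attribute
#'   `n_eligible` (the number of eligible cells). If fewer eligible cells than
#'   `n` exist, all of them are returned with a warning (never sampled with
#'   replacement).
#' @export
sample_disk_pseudoabsences <- function(occ, domain, n = 5000,
                                       r_min_km = 130, r_max_km = 250,
                                       seed = 1L) {
  stopifnot(r_min_km < r_max_km, NROW(occ) >= 1)
  xy <- rg_coords(domain)
  valid <- !is.na(as.vector(domain$values))
  if (!any(valid)) stop("no valid cells in domain")
  cand <- xy[valid, , drop = FALSE]
  nearest <- rep(Inf, nrow(cand))
  for (i in seq_len(NROW(occ))) {
    nearest <- pmin(nearest,
                    gc_distance_km(c(occ$lon[i], occ$lat[i]), cand))
  }
  eligible <- which(nearest >= r_min_km & nearest <= r_max_km)
  if (length(eligible) == 0) stop("no eligible cells in the annulus")
  if (length(eligible) < n) {
    warning(sprintf("only %d eligible cells for %d requested pseudo-absences",
                    length(eligible), n))
    pick <- eligible
  } else {
    set.seed(seed)
    pick <- sample(eligible, n)
  }
  out <- data.frame(lon = cand[pick, 1], lat = cand[pick, 2])
  attr(out, "n_eligible") <- length(eligible)
  out
}

#' Equalize total presence and pseudo-absence weight
#'
#' Pseudo-absences get weight 1; presences get `n_absences / n_presences`, so
#' both classes carry the same total weight regardless of their imbalance.
#'
#' @param table data.frame with a `label` column (1 presence, 0 absence).
#' @return `table` with a `weight` column replaced/added.
#' @export
assign_case_weights <- function(table) {
  n1 <- sum(table$label == 1); n0 <- sum(table$label == 0)
  if (n1 == 0) stop("no presences")
  if (n0 == 0) stop("no pseudo-absences")
  table$weight <- ifelse(table$label == 1, n0 / n1, 1)
  table
}

#' Assemble a presence/pseudo-absence training table
#'
#' Extracts predictor values at presence and pseudo-absence locations from a
#' raster stack, labels the rows, equalizes class weights and drops rows with
#' any missing predictor.
#'
#' @param stack named list of predictor `raster_grid`s.
#' @param presences,absences data.frames with `lon`, `lat`.
#' @return data.frame with the predictor columns plus `label`, `weight`,
#'   `lon`, `lat`.
#' @export
build_training_table <- function(stack, presences, absences) {
  pts <- rbind(data.frame(lon = presences$lon, lat = presences$lat, label = 1),
               data.frame(lon = absences$lon, lat = absences$lat, label = 0))
  X <- as.data.frame(lapply(stack, function(g) rg_extract(g, pts$lon, pts$lat)))
  tab <- cbind(X, pts[c("label", "lon", "lat")])
  tab <- tab[stats::complete.cases(X), , drop = FALSE]
  assign_case_weights(tab)
}

#' Boosted-tree tuning grid
#'
#' The hyperparameter combinations evaluated by [fit_enm()]. The default
#' value lists mirror the customary first-pass grid for presence/
#' pseudo-absence boosted regression trees (shrinkage 0.01/0.1/0.3, tree
#' depth 1/3/5, minimum node size 5/10/15, bag fraction 0.65/0.8/1), with up
#' to `n_trees_max` trees and the cross-validation-optimal tree count
#' selected per combination.
#'
#' @param shrinkage learning rates.
#' @param interaction_depth maximum tree depths.
#' @param min_obs_in_node minimum observations (hessian weight) per leaf.
#' @param bag_fraction row subsampling fractions in (0, 1].
#' @param n_trees_max maximum number of boosting iterations.
#' @param train_fraction fraction of data used for the reported holdout RMSE.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @return object of class `enm_tuning_grid`.
#' @export
enm_tuning_grid <- function(shrinkage = c(0.01, 0.1, 0.3),
                            interaction_depth = c(1, 3, 5),
                            min_obs_in_node = c(5, 10, 15),
                            bag_fraction = c(0.65, 0.8, 1),
                            n_trees_max = 20000L,
                            train_fraction = 0.8,
                            cv_folds = 10L) {
  stopifnot(length(shrinkage) > 0, length(interaction_depth) > 0,
            length(min_obs_in_node) > 0, length(bag_fraction) > 0,
            all(bag_fraction > 0 & bag_fraction <= 1), cv_folds >= 2)
  structure(list(shrinkage = shrinkage,
                 interaction_depth = as.integer(interaction_depth),
                 min_obs_in_node = min_obs_in_node,
                 bag_fraction = bag_fraction,
                 n_trees_max = as.integer(n_trees_max),
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds)),
            class = "enm_tuning_grid")
}

# xgboost parameter list for one grid combination.
xgb_params <- function(combo, seed) {
  list(objective = "binary:logistic", eval_metric = "rmse",
       eta = combo$shrinkage, max_depth = combo$interaction_depth,
       min_child_weight = combo$min_obs_in_node,
       subsample = combo$bag_fraction, nthread = 1, seed = seed)
}

#' Cross-validated RMSE of every grid combination
#'
#' For one combination and fixed folds, fits the boosted trees on each
#' training split (Bernoulli/logistic loss, case weights honoured) and logs
#' the per-iteration RMSE of predicted probability vs label on the held-out
#' fold; per-round RMSEs are averaged over folds and the minimizing round is
#' the combination's tree count. Exposed separately from [fit_enm()] so tests
#' can re-evaluate the grid independently.
#'
#' @param table training table (see [build_training_table()]).
#' @param grid an [enm_tuning_grid()].
#' @param seed RNG seed (controls fold assignment and bagging).
#' @param predictors predictor column names; default every column except
#'   `label`, `weight`, `lon`, `lat`.
#' @return data.frame, one row per combination, with the grid values,
#'   `n_trees` (CV-optimal round) and `cv_rmse`.
#' @export
enm_cv_grid <- function(table, grid, seed = 1L, predictors = NULL) {
  if (is.null(predictors))
    predictors <- setdiff(names(table), c("label", "weight", "lon", "lat"))
  X <- as.matrix(table[predictors])
  if (!all(is.finite(X))) stop("non-finite predictor values in training table")
  y <- table$label
  w <- if (!is.null(table$weight)) table$weight else rep(1, nrow(table))
  set.seed(seed)
  fold <- sample(rep(seq_len(grid$cv_folds), length.out = nrow(X)))
  combos <- expand.grid(shrinkage = grid$shrinkage,
                        interaction_depth = grid$interaction_depth,
                        min_obs_in_node = grid$min_obs_in_node,
                        bag_fraction = grid$bag_fraction,
                        KEEP.OUT.ATTRS = FALSE)
  combos$n_trees <- NA_integer_; combos$cv_rmse <- NA_real_
  for (ci in seq_len(nrow(combos))) {
    logs <- matrix(NA_real_, grid$n_trees_max, grid$cv_folds)
    for (k in seq_len(grid$cv_folds)) {
      tr <- fold != k
      dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr],
                                     weight = w[tr], nthread = 1)
      dval <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], label = y[!tr],
                                   nthread = 1)
      fit <- xgboost::xgb.train(params = xgb_params(combos[ci, ], seed),
                                data = dtrain, nrounds = grid$n_trees_max,
                                evals = list(val = dval), verbose = 0)
      logs[, k] <- attributes(fit)$evaluation_log$val_rmse
    }
    mean_rmse <- rowMeans(logs)
    combos$n_trees[ci] <- which.min(mean_rmse)
    combos$cv_rmse[ci] <- min(mean_rmse)
  }
  combos
}

#' Fit a tuned boosted-tree ecological niche model
#'
#' Evaluates every combination of the tuning grid by k-fold cross-validation
#' (see [enm_cv_grid()]), selects the combination with the lowest CV RMSE of
#' predicted probability vs label (ties broken by fewer trees, then smaller
#' shrinkage), and refits it on the full table. An optional holdout RMSE at
#' `train_fraction` is reported alongside.
#'
#' @inheritParams enm_cv_grid
#' @return an object of class `enm`: the fitted booster plus `best_params`,
#'   `cv_rmse`, `cv_table`, `holdout_rmse`, `predictor_names` and the
#'   training table.
#' @seealso [predict.enm()], [variable_contributions()], [evaluate_boyce()]
#' @export
fit_enm <- function(table, grid = enm_tuning_grid(), seed = 1L,
                    predictors = NULL) {
  if (is.null(predictors))
    predictors <- setdiff(names(table), c("label", "weight", "lon", "lat"))
  cv <- enm_cv_grid(table, grid, seed, predictors)
  best_rmse <- min(cv$cv_rmse)
  cand <- cv[cv$cv_rmse <= best_rmse + 1e-12, , drop = FALSE]
  cand <- cand[order(cand$n_trees, cand$shrinkage), , drop = FALSE]
  best <- cand[1, ]
  X <- as.matrix(table[predictors]); y <- table$label
  w <- if (!is.null(table$weight)) table$weight else rep(1, nrow(table))
  dall <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
  booster <- xgboost::xgb.train(params = xgb_params(best, seed), data = dall,
                                nrounds = best$n_trees, verbose = 0)
  # holdout RMSE at train_fraction, reported for reference only
  set.seed(seed + 1L)
  n_tr <- floor(grid$train_fraction * nrow(X))
  tr <- sample(nrow(X), n_tr)
  holdout_rmse <- if (n_tr < nrow(X)) {
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr],
                                weight = w[tr], nthread = 1)
    fit <- xgboost::xgb.train(params = xgb_params(best, seed), data = dtr,
                              nrounds = best$n_trees, verbose = 0)
    p <- stats::predict(fit, X[-tr, , drop = FALSE])
    sqrt(mean((p - y[-tr])^2))
  } else NA_real_
  structure(list(booster = booster,
                 best_params = as.list(best[c("shrinkage", "interaction_depth",
                                              "min_obs_in_node", "bag_fraction",
                                              "n_trees")]),
                 cv_rmse = best$cv_rmse, cv_table = cv,
                 holdout_rmse = holdout_rmse,
                 predictor_names = predictors,
                 table = table, grid = grid, seed = seed),
            class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  cat("Boosted-tree ecological niche model\n")
  cat(sprintf("  %d presences, %d pseudo-absences, %d predictors\n",
              sum(x$table$label == 1), sum(x$table$label == 0),
              length(x$predictor_names)))
  bp <- x$best_params
  cat(sprintf("  tuned: shrinkage=%g, depth=%d, min.obs=%g, bag=%g, trees=%d\n",
              bp$shrinkage, bp$interaction_depth, bp$min_obs_in_node,
              bp$bag_fraction, bp$n_trees))
  cat(sprintf("  CV RMSE = %.4f (grid of %d combinations)\n",
              x$cv_rmse, nrow(x$cv_table)))
  invisible(x)
}

#' @export
summary.enm <- function(object, ...) {
  contr <- variable_contributions(object)
  out <- list(best_params = object$best_params, cv_rmse = object$cv_rmse,
              holdout_rmse = object$holdout_rmse, contributions = contr)
  class(out) <- "summary.enm"
  out
}

#' @export
print.summary.enm <- function(x, ...) {
  bp <- x$best_params
  cat("Tuned boosted-tree ENM\n")
  cat(sprintf("  shrinkage=%g, depth=%d, min.obs=%g, bag=%g, trees=%d\n",
              bp$shrinkage, bp$interaction_depth, bp$min_obs_in_node,
              bp$bag_fraction, bp$n_trees))
  cat(sprintf("  CV RMSE = %.4f; holdout RMSE = %.4f\n",
              x$cv_rmse, x$holdout_rmse))
  cat("  Variable contributions (%):\n")
  for (nm in names(sort(x$contributions, decreasing = TRUE)))
    cat(sprintf("    %-12s %6.1f\n", nm, x$contributions[[nm]]))
  invisible(x)
}

#' Predict suitability from a fitted ENM
#'
#' `newdata` may be a data.frame/matrix of predictor columns (returns a
#' probability vector) or a named list of `raster_grid`s (returns a
#' suitability `raster_grid`, nodata propagated). Fitted values on the
#' training table are returned when `newdata` is missing.
#'
#' @param object an `enm`.
#' @param newdata predictors; see Details.
#' @param ... unused.
#' @export
predict.enm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$table
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, inherits, TRUE, "raster_grid")))
    return(project_model(object, newdata))
  missing <- setdiff(object$predictor_names, colnames(newdata))
  if (length(missing))
    stop("missing predictor(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[object$predictor_names])
  stats::predict(object$booster, X)
}

#' Continuous Boyce index
#'
#' Presence-only evaluation: moving windows over the suitability range; per
#' window the predicted-to-expected ratio P/E = (fraction of presence
#' predictions inside) / (fraction of background predictions inside); the
#' index is the Spearman rank correlation between P/E and the window
#' midpoint, in \[-1, 1\]. Windows whose expected fraction is zero are
#' skipped.
#'
#' @param presence_pred suitability predicted at presence sites, in \[0, 1\].
#' @param background_pred suitability over the background, in \[0, 1\].
#' @param n_windows number of moving windows (default 101).
#' @param window_width_fraction window width as a fraction of the prediction
#'   range (default 1/10).
#' @return the Boyce index (numeric scalar). Constant predictions are an
#'   error (the correlation is undefined).
#' @export
evaluate_boyce <- function(presence_pred, background_pred, n_windows = 101,
                           window_width_fraction = 0.1) {
  stopifnot(length(presence_pred) > 0, length(background_pred) > 0,
            all(presence_pred >= 0 & presence_pred <= 1),
            all(background_pred >= 0 & background_pred <= 1))
  r <- range(c(presence_pred, background_pred))
  if (diff(r) == 0) stop("constant predictions: Boyce index undefined")
  W <- window_width_fraction * diff(r)
  centers <- seq(r[1] + W / 2, r[2] - W / 2, length.out = n_windows)
  pe <- vapply(centers, function(cc) {
    lo <- cc - W / 2; hi <- cc + W / 2
    E <- mean(background_pred >= lo & background_pred <= hi)
    if (E == 0) return(NA_real_)
    P <- mean(presence_pred >= lo & presence_pred <= hi)
    P / E
  }, numeric(1))
  ok <- !is.na(pe)
  if (sum(ok) < 3) stop("too few usable windows for the Boyce index")
  b <- suppressWarnings(stats::cor(pe[ok], centers[ok], method = "spearman"))
  if (is.na(b)) stop("Boyce index undefined (constant P/E ratio)")
  b
}

#' Moran's I residual correlogram
#'
#' Splits the pairwise great-circle distances into `n_classes` equal-width
#' classes and computes, per class, Moran's I with binary weights (`w_ij = 1`
#' inside the class) and a permutation p-value. Classes without pairs are
#' reported as `NA` rows.
#'
#' @param residuals numeric residuals, one per point (>= 10 points).
#' @param points data.frame or matrix with `lon`, `lat`.
#' @param n_classes number of distance classes (default 10).
#' @param n_perm permutation count for the p-values (default 199).
#' @param seed RNG seed for the permutations.
#' @return data.frame with `mean_dist_km`, `moran_i`, `p_value`, `n_pairs`.
#' @export
residual_correlogram <- function(residuals, points, n_classes = 10,
                                 n_perm = 199, seed = 1L) {
  pts <- if (is.data.frame(points)) cbind(points$lon, points$lat)
         else as.matrix(points)
  n <- length(residuals)
  stopifnot(n >= 10, nrow(pts) == n)
  z <- residuals - mean(residuals)
  s2 <- sum(z^2)
  d <- gc_distance_matrix_km(pts)
  pair_i <- row(d)[upper.tri(d)]; pair_j <- col(d)[upper.tri(d)]
  pair_d <- d[upper.tri(d)]
  breaks <- seq(0, max(pair_d), length.out = n_classes + 1)
  cls <- cut(pair_d, breaks, include.lowest = TRUE, labels = FALSE)
  set.seed(seed)
  perms <- replicate(n_perm, sample(z))
  out <- data.frame(mean_dist_km = rep(NA_real_, n_classes),
                    moran_i = NA_real_, p_value = NA_real_,
                    n_pairs = 0L)
  for (k in seq_len(n_classes)) {
    sel <- which(cls == k)
    out$n_pairs[k] <- length(sel)
    if (length(sel) == 0) next
    i <- pair_i[sel]; j <- pair_j[sel]
    moran <- function(zz) (n / length(sel)) * sum(zz[i] * zz[j]) / sum(zz^2)
    I <- moran(z)
    Iperm <- apply(perms, 2, moran)
    out$mean_dist_km[k] <- mean(pair_d[sel])
    out$moran_i[k] <- I
    out$p_value[k] <- (1 + sum(abs(Iperm) >= abs(I))) / (n_perm + 1)
  }
  out
}

#' Relative variable contributions
#'
#' Per-predictor share of the model's total loss reduction across all splits
#' (`method = "gain"`, the default), or mean increase in RMSE when the
#' predictor is permuted (`method = "permutation"`); either way normalized to
#' sum to 100.
#'
#' @param model an `enm`.
#' @param method `"gain"` or `"permutation"`.
#' @param n_perm permutation repeats (permutation method only).
#' @param seed RNG seed (permutation method only).
#' @return named numeric vector of percentages summing to 100.
#' @export
variable_contributions <- function(model, method = c("gain", "permutation"),
                                   n_perm = 5, seed = 1L) {
  method <- match.arg(method)
  vars <- model$predictor_names
  raw <- stats::setNames(numeric(length(vars)), vars)
  if (method == "gain") {
    tree <- xgboost::xgb.model.dt.tree(model = model$booster)
    splits <- tree[tree$Feature != "Leaf", ]
    if (nrow(splits)) {
      gain <- rowsum(splits$Gain, splits$Feature)
      raw[rownames(gain)] <- gain[, 1]
    }
  } else {
    X <- as.matrix(model$table[vars]); y <- model$table$label
    base <- sqrt(mean((stats::predict(model$booster, X) - y)^2))
    set.seed(seed)
    for (v in vars) {
      inc <- numeric(n_perm)
      for (r in seq_len(n_perm)) {
        Xp <- X; Xp[, v] <- sample(Xp[, v])
        inc[r] <- sqrt(mean((stats::predict(model$booster, Xp) - y)^2)) - base
      }
      raw[v] <- max(mean(inc), 0)
    }
  }
  if (sum(raw) == 0) raw[] <- 1
  100 * raw / sum(raw)
}

# Partial dependence of the fitted probability on `vars` at `grid`
# (data.frame, one column per var): other predictors integrated over the
# training rows. Returns one mean prediction per grid row.
partial_dependence <- function(model, grid, chunk = 2e5) {
  X <- as.matrix(model$table[model$predictor_names])
  ng <- nrow(grid); n <- nrow(X)
  out <- numeric(ng)
  rows_per_chunk <- max(1L, floor(chunk / n))
  for (start in seq(1L, ng, by = rows_per_chunk)) {
    idx <- start:min(ng, start + rows_per_chunk - 1L)
    big <- X[rep(seq_len(n), times = length(idx)), , drop = FALSE]
    for (v in names(grid))
      big[, v] <- rep(grid[[v]][idx], each = n)
    p <- stats::predict(model$booster, big)
    out[idx] <- colMeans(matrix(p, nrow = n))
  }
  out
}

#' Friedman's H interaction statistic for a predictor pair
#'
#' Measures how much of the joint partial-dependence surface of the pair is
#' not explained by the sum of the two univariate partial-dependence curves:
#' `H = sqrt( sum((PD_jk - PD_j - PD_k)^2) / sum(PD_jk^2) )` over a quantile
#' grid (all functions centered). 0 means additivity.
#'
#' @param model an `enm`.
#' @param pair character vector of two predictor names.
#' @param grid_points quantile-grid resolution per axis (default 50).
#' @return non-negative scalar H.
#' @export
interaction_strength <- function(model, pair, grid_points = 50) {
  stopifnot(length(pair) == 2, all(pair %in% model$predictor_names))
  q <- function(v) unique(stats::quantile(
    model$table[[v]], probs = (seq_len(grid_points) - 0.5) / grid_points,
    names = FALSE))
  g1 <- q(pair[1]); g2 <- q(pair[2])
  pd1 <- partial_dependence(model, stats::setNames(data.frame(g1), pair[1]))
  pd2 <- partial_dependence(model, stats::setNames(data.frame(g2), pair[2]))
  gg <- expand.grid(g1, g2, KEEP.OUT.ATTRS = FALSE)
  names(gg) <- pair
  pd12 <- partial_dependence(model, gg)
  c1 <- pd1 - mean(pd1); c2 <- pd2 - mean(pd2); c12 <- pd12 - mean(pd12)
  joint <- c12
  additive <- rep(c1, times = length(g2)) + rep(c2, each = length(g1))
  num <- sum((joint - additive)^2)
  den <- sum(joint^2)
  if (den == 0) return(0)
  sqrt(num / den)
}

#' Marginal (partial-dependence) response curve
#'
#' The model's partial prediction along one predictor's observed range, the
#' other predictors integrated over the training distribution.
#'
#' @param model an `enm`.
#' @param predictor predictor name.
#' @param grid_points number of evaluation points (default 50).
#' @return data.frame with `value` and `prediction`.
#' @export
marginal_response <- function(model, predictor, grid_points = 50) {
  stopifnot(predictor %in% model$predictor_names)
  v <- model$table[[predictor]]
  grid <- seq(min(v), max(v), length.out = grid_points)
  pd <- partial_dependence(
    model, stats::setNames(data.frame(grid), predictor))
  data.frame(value = grid, prediction = pd)
}

#' Plot marginal response curves of a fitted ENM
#'
#' @param x an `enm`.
#' @param predictors which predictors (default all).
#' @param grid_points evaluation points per curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.enm <- function(x, predictors = x$predictor_names, grid_points = 50,
                     ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(predictors)))
  on.exit(graphics::par(old))
  for (v in predictors) {
    mr <- marginal_response(x, v, grid_points)
    graphics::plot(mr$value, mr$prediction, type = "l", xlab = v,
                   ylab = "partial prediction", ...)
  }
  invisible(x)
}
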