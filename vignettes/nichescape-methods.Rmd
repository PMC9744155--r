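---
title: "Methods: suitability, projection and connectivity modelling in nichescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suitability, projection and connectivity modelling in nichescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichescape)
```

## Overview

`nichescape` implements a presence-only distribution-and-connectivity
workflow for wide-ranging, forest-bound species: an ecological niche model
(ENM) on climate predictors, projection to future climates with
extrapolation control, refinement of the climatic prediction by topography
and river habitat, circuit-theory corridor modelling on the refined map, and
SVM-based niche-overlap and protected-area gap analyses. All stages operate
on a lightweight in-package raster container (`raster_grid`: a matrix plus
lon/lat extent, cell-center registration, `NA` nodata) and are exercised
end-to-end on synthetic landscapes with known generating truth.

## Occurrence preparation

Raw records pass three filters, in order: records dated before a cutoff year
(default 1970) are dropped; records whose coordinate precision implies a
positional uncertainty coarser than 2.5 arc-minutes are dropped (uncertainty
is taken as half the last reported decimal, `0.5 * 10^-decimals` degrees);
records sharing a 2.5 arc-minute cell are deduplicated. Records with a
*missing* year are kept: the year rule excludes records known to predate the
cutoff, and discarding undated records would silently shrink datasets whose
older literature rarely timestamps localities. Filtering is idempotent.

Pairwise inter-point summaries use great-circle (haversine) distances on a
sphere of radius 6371.0088 km. A planar option exists because some GIS
workflows report projected Euclidean distances; over a continental extent
the two differ by a few percent, so both are exposed and the choice is
explicit in the function call.

Longitude groups (defaults West `[-15, 0)`, Central `[0, 15)`, East
`[15, 50)`) use half-open intervals: published range descriptions often
repeat the shared endpoint, and a tie rule must be fixed for records exactly
on a break. The left-closed convention assigns each break to the group on
its right.

## The niche model

**Collinearity screen.** Iterative VIF selection: regress each candidate on
the others, `VIF = 1/(1 - R^2)`, remove the worst while it is at or above 10
(the `>=` rule means a predictor sitting exactly at the threshold is
removed; an exactly collinear predictor is removed first with infinite VIF).

**Pseudo-absences.** Background points are sampled uniformly among raster
cells whose great-circle distance to the *nearest* presence lies in an
annulus, by default 130–250 km. The inner radius reflects the species'
recorded daily movement capacity (~130 km for the giant noctule, the
motivating species), so cells that resident animals could plausibly use are
never labelled absent; the outer radius keeps the contrast informative
rather than trivially easy. When fewer eligible cells exist than requested,
all of them are returned with a warning — never resampled with replacement,
which would silently duplicate rows. Setting `r_min_km = 0` with a large
`r_max_km` degenerates to plain background sampling, which the synthetic
tests use where the annulus itself is not under test.

**Weights.** Pseudo-absences get weight 1 and presences `n0/n1`, so the two
classes carry equal total weight however unbalanced the design (260
presences against 5,000 pseudo-absences gives presence weight ≈ 19.23).

**Fitting and tuning.** Boosted regression trees with logistic loss, fitted
through xgboost. The tuning grid crosses shrinkage, tree depth, minimum node
weight and bag fraction (defaults 0.01/0.1/0.3 x 1/3/5 x 5/10/15 x
0.65/0.8/1); for each combination, k-fold cross-validation (default 10
folds) logs the held-out RMSE of predicted probability vs the 0/1 label at
every boosting iteration up to `n_trees_max`, the per-iteration RMSEs are
averaged over folds, and the minimizing iteration is that combination's tree
count. The winning combination minimizes CV RMSE, with ties broken by fewer
trees then smaller shrinkage; it is refit on the full table. A holdout RMSE
at `train_fraction` (default 0.8) is reported alongside but plays no role in
selection — cross-validation is the single selection criterion, which keeps
the tuning deterministic given the seed and auditable by exhaustive
re-evaluation. One mapping note: xgboost's `min_child_weight` bounds the
hessian sum of a leaf, not its row count, so "minimum observations per node"
is honoured in a weighted (and for logistic loss, slightly conservative)
sense.

**Evaluation.**

* *Continuous Boyce index*: 101 moving windows of width one tenth of the
  prediction range; per window, the predicted-to-expected ratio
  `P/E` (share of presence predictions inside / share of background
  predictions inside); the index is the Spearman correlation of `P/E` with
  the window midpoint. Windows with zero expected share are skipped and
  constant predictions are an error rather than a number. One property worth
  knowing: under *no* association (presences a uniform subsample of the
  background), a single draw of the index is not small — it is a rank
  correlation of strongly autocorrelated noise and has a standard deviation
  near 0.3 regardless of sample size. Its *expectation* is zero, so the
  package's no-information tests assert the mean over 20 seeds rather than
  any single draw.
* *Contributions*: per-predictor share of total split gain, normalized to
  100% (a permutation-importance alternative is available by flag; both are
  reported on the same 0–100 scale).
* *Interactions*: Friedman's H from the partial-dependence decomposition on
  a quantile grid (default 50 x 50): the centered joint surface minus the
  sum of the centered univariate curves, relative to the joint surface.
* *Residual correlograms*: Moran's I per equal-width distance class with
  binary within-class weights, permutation p-values (default 199 shuffles —
  the smallest round count giving a 0.005 resolution at two digits; the
  count is configurable).

## Projection, MESS and the GCM ensemble

Projection applies the fitted ensemble cell-by-cell; nodata in any predictor
propagates. Extrapolation is quantified by MESS: per cell and predictor,
with `f` the percentage of calibration values strictly below the cell value,
similarity is `100 (p - min)/(max - min)` when `f = 0`, `2f` when
`0 < f <= 50`, `2(100 - f)` when `50 < f < 100`, and `100 (max - p)/(max -
min)` when `f = 100`; the cell score is the minimum over predictors, and
negative scores flag novel conditions. MESS is computed only on the
predictors the model actually uses. Because `f` counts values strictly
below, the "median ⇒ 100" anchor holds exactly for even-sized references
(where exactly half the values lie below the median); for odd sizes the
median coincides with an observation and `f` is marginally below 50.

Per-GCM projections of one scenario-year are combined by MESS-weighted
averaging: `w_g = max(MESS_g, 0) + 1e-6` and the combined suitability is
`sum(w_g S_g)/sum(w_g)`. This is the package's own operational definition of
similarity-weighted ensemble combination: a GCM projecting into novel
conditions is suppressed to an epsilon share, identical projections pass
through unchanged, and the output is always a convex combination of the
inputs. The epsilon floor exists only so cells where every GCM extrapolates
still return the (equal-weighted) mean rather than 0/0.

Suitability is reclassified to 1–10 by equal intervals,
`class = min(floor(10 v) + 1, 10)`; bin edges belong to the upper bin so
that class 10 is reachable and 0.10 maps to class 2.

## The weighted model

Three 1–10 layers are combined cell-wise: reclassified climate suitability,
an elevation-preference layer, and a river-functionality layer.

* *Elevation preference*: DEM values at occurrences are binned into 100 m
  intervals; bin counts are min–max rescaled to 1–10 with half-up rounding
  (`1 + floor(9 (c - min)/(max - min) + 0.5)`); bins outside the occupied
  range score 1; if every occupied bin has the same count the degenerate
  rescale maps them all to 10 (the same rule covers a single occupied bin).
* *River functionality*: segments with Strahler order > 4 (the major
  watercourses the species uses to roost, forage and move) are scored
  `CSI - URB` — connectivity status minus urbanization pressure, both
  percentages — min–max rescaled to 1–10, and rasterized with the maximum
  score per cell; cells without rivers score 1 rather than nodata so the
  overlay is defined everywhere.
* *Overlay*: `round_half_up(w_c C + w_e E + w_r R)` clamped to 1–10; finer
  layers are first upscaled to the climate grid (mean aggregation for
  elevation classes, max for river classes, mirroring how GIS overlay tools
  treat continuous vs categorical layers). The weights are **not** part of
  the scientific record this workflow derives from; the package defaults to
  (0.5, 0.25, 0.25) — climate dominant, the two refinements equal — and
  ships `overlay_weight_sweep()` to quantify how sensitive the map is to
  that choice instead of pretending a single truth. Half-up rounding is used
  everywhere an integer class is produced, chosen once for consistency
  because the GIS tools this emulates do not document their tie rule.

Old-growth forest points become polygons by `radius_m =
sqrt(area_ha * 10^4 / pi)` (the radius of the circle with the reported
area), a geodesic buffer of that radius, and optional refinement by a
forest mask that can only remove area.

## Connectivity

The weighted suitability map is read directly as conductance ("suitability
as permeability"): each valid cell is a node with conductance equal to its
class; adjacent cells are joined with edge conductance equal to the mean of
the two cell values, and diagonal edges (default eight-neighborhood) are
divided by sqrt(2) for the longer step. An inverted-resistance transform
(`R = 11 - ws`) and four-neighborhood are available as flags for sensitivity
checks.

Pairwise mode grounds one focal node, injects a unit current at the other,
and solves the reduced graph-Laplacian system; the effective resistance is
the source potential, and per-cell current magnitude is half the sum of
absolute incident edge currents plus half the absolute net injection — so
pass-through cells report their throughflow and source/ground cells their
full injected current, keeping Kirchhoff totals exact. Cumulative maps sum
over all unordered pairs (summation, rather than per-pair maxima, is the
convention of the circuit software this emulates). Advanced mode ties every
cell inside the destination polygons to zero potential and solves once with
all stated injections; a destination polygon smaller than one cell grounds
the cell its vertices fall in. The linear systems are solved by sparse
Cholesky factorization (Matrix); at the package's problem sizes a direct
solve is exact, fast, and avoids iteration-tolerance knobs entirely.
Focal points snap to their containing cell; coincident focal cells merge
with a warning; pairs in disconnected components report infinite resistance
and contribute no current.

Change between scenarios is summarized cell-wise by
`SCCI = (F - C)/(F + C)` in [-1, 1], with 0 where both currents are zero;
+1 is connectivity fully gained, -1 fully lost, and the index is
antisymmetric under swapping the two maps. Forests are classed *reachable*
when their polygon lies within 130 km (the recorded maximum daily foraging
transit) of any occurrence.

## Niche overlap and gap analysis

Two labelled point clouds in (pooled z-scored) predictor space are declared
*non-overlapping* exactly when a two-class SVM with a large
misclassification penalty (default `C = 10^6`, a hard-margin approximation)
attains 100% training accuracy — perfect separation — under the chosen
kernel: linear, or 2nd-degree polynomial `(gamma x.x' + 1)^2` with
`gamma = 1/n_predictors`. Identical points under both labels short-circuit
to *overlap* without fitting. The pairwise matrix over many groups is
assembled one-vs-one and is symmetric by construction; undersized groups
(fewer than 3 points) are marked untested. Note the verdict is a geometric
statement about the training points, not a statistical test; support-vector
counts are reported as a complexity diagnostic.

Gap analysis classifies each occurrence by point-in-polygon membership as
`none`, `natura2000`, `national` or `both` (where the two protection kinds
co-occur), and measures the great-circle distance to the nearest forest
polygon boundary (zero inside). Polygon rings are closed automatically with
a warning when unclosed; self-intersecting polygons are the caller's
responsibility, as the package deliberately carries no computational-
geometry engine.

## The synthetic landscape generator

`generate_landscape()` emulates the statistical structure the analysis
assumes, with full determinism under a seed:

* predictors are Gaussian-filtered white noise (filter sd 5 cells by
  default) plus a latitudinal gradient, standardized; requested collinear
  pairs are built by exact orthogonalization so the sample correlation hits
  the target;
* future stacks add a per-GCM trend (scaled 1x/2x/3x over the 2030/2050/2070
  horizons, so later horizons drift further) plus smoothed spatial noise of
  a per-GCM sd, over 2 SSPs x 3 years x 3 synthetic GCMs;
* occurrences are drawn cell-wise with probability proportional to
  `plogis(intercept + beta . predictors)`, jittered within the cell, with
  years in 1990–2020 and full-precision coordinates so the default filters
  keep them;
* rivers are random-walk polylines with Strahler orders always covering both
  sides of the order-4 selection threshold, and CSI/URB percentages; forest
  areas are log-uniform on 1–10,000 ha; protected rectangles always include
  each protection kind.

What it deliberately does **not** emulate: the physical semantics of real
bioclimatic variables (units, bounded supports, temperature-precipitation
covariance), sampling bias in occurrence records, spatially structured
nodata (seas, political borders), or realistic river topology. Passing
recovery tests on these landscapes therefore demonstrates that the
machinery is correct — that the pipeline recovers a known generating truth —
not that any particular real-world inference is right.

## Numerical choices and problem sizes

Half-up rounding for all 1–10 class arithmetic; strictly-below counting in
MESS; epsilon floor `10^-6` in the ensemble weights; sparse direct solves
for all circuit systems; SVM penalty `10^6`; permutation count 199;
great-circle radius 6371.0088 km everywhere. The test-suite and acceptance
runs use landscapes of 40 x 40 cells (0.5-degree resolution over a
20 x 20-degree window), 150–600 presences, 300–1,500 pseudo-absences,
tuning grids of up to four combinations with up to 150 trees and 3 folds,
and 10-focal-point circuit solves — sizes chosen so the full pipeline (not
a stub of it) runs in seconds while every contract stays binding at scale.

## Known limitations

* The raster container assumes one shared lon/lat grid; there is no
  reprojection or resampling beyond integer-factor aggregation.
* Cell areas and the planar-distance option use spherical approximations;
  sub-kilometre accuracy at high latitudes is out of scope.
* The cumulative-current convention (sum over pairs) and the
  suitability-as-conductance reading are fixed conventions of this
  implementation; both have documented flags or alternatives where a
  sensitivity check is cheap.
* The SVM overlap verdict is binary and sample-size sensitive: more points
  can only break separability, never restore it.
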