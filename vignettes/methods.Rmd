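---
title: "Methods: seasonal spatial analysis of green space and negative emotions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal spatial analysis of green space and negative emotions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures implemented in
`greenmood`, the assumptions behind them, the tunable parameters that
matter, and the design choices we made where the methodology was
genuinely open. It states no empirical result beyond what the package's
own tests and `scripts/acceptance.R` compute.

## The analysis in one paragraph

Geotagged social-media posts labeled by sentiment are filtered to
negative posts per meteorological season, converted to a continuous
intensity surface by planar kernel density estimation, averaged over
community footprints, and standardized by population to give a
community × season negative-emotion index. Each community also carries
14 covariates describing its green space (quantity, quality, landscape
pattern) and controls (residential density, female share, night light,
lockdown intensity). Spatial clustering of the index is quantified by
global Moran's I and LISA. The association between covariates and the
index is modelled by a geographically weighted random forest (GWRF) —
one locally weighted forest per community over its adaptive
neighborhood — benchmarked against a global random forest and
geographically weighted regression (GWR). Fitted models are interpreted
through Shapley values (global importance and per-community dominant
factors), seasonal partial-dependence curves with turning-point
detection, and signed local effect surfaces.

## Emotion indicator

**KDE.** The surface is `f(s) = sum_i K((s - s_i)/h) / (n h^2)`,
evaluated at grid-cell centers. The default kernel is the quartic
(biweight) `K(u) = (3/pi)(1 - |u|^2)^2` on the unit disk — the kernel
used by common desktop-GIS density tools — with Gaussian and uniform
alternatives for testing. Each kernel integrates to one, so an interior
surface integrates to ≈ 1; this mass-conservation property is tested at
1%. The bandwidth is not dictated by the study design; we default to
1,000 m, the same scale as the walking catchment used for
accessibility, and expose it in the configuration. Output cell size
defaults to 250 m (extent/cell ≈ 120 cells per side at the default
30 km extent); community footprints must contain at least one cell
center or the indicator refuses to aggregate.

**Standardization.** The community's `raw_density` is the mean surface
value over the cells whose centers fall in its footprint (robust to
surface curvature, unlike centroid sampling), and the index is
`raw_density / (population / 10,000)` — density per 10,000 residents.
The per-10,000 scale is a reporting convention; any fixed scale gives
the same ranks, correlations and model fits. Footprints are
nearest-centroid (Voronoi) cells, which is exactly how the synthetic
city defines community polygons.

**Seasons.** March–May is spring, June–August summer,
September–November autumn, and December, January, February winter.
Working within a single calendar year, the winter window pools January,
February and December of that same year; with multi-year data one would
instead roll December into the following winter. Boundary days belong
to the season they open.

**Classifier metrics.** The sentiment classifier itself is out of scope
(synthetic posts carry labels), but `classification_metrics()`
implements the three-class confusion-matrix summary (accuracy,
per-class precision/recall/F1, unweighted macro averages) used to
evaluate such classifiers. A class never predicted receives precision
0 rather than NaN.

## Green-space covariates

* **NDVI** is `(NIR - Red)/(NIR + Red)` cellwise; cells with
  `NIR + Red = 0` carry no signal, become nodata, and are excluded from
  community means.
* **Street-view scores** (greenery, openness, walkability) aggregate in
  two levels — mean over available viewing directions per point, then
  mean over points per community — never as a pooled mean, which would
  overweight points with more directions.
* **Accessibility** is the count of destinations within a 1 km network
  walking catchment, with a closed boundary (exactly 1,000 m counts).
  Distances arrive as a table; the package does not embed a router.
  Whether to normalize the count into an index is left to a documented
  hook (the count is the default).
* **Landscape metrics** follow the FRAGSTATS conventions: patches are
  8-connected components of equal-class cells (4-connectivity
  selectable); LPI is the largest patch's share of the landscape in
  percent; PD is patches per 100 ha; ED is meters of class boundary per
  hectare with the landscape border excluded; SHDI is the Shannon
  entropy of class area proportions in nats. All four are computed at
  landscape level per community raster window and are verified against
  a brute-force oracle on random small rasters.
* **Lockdown intensity** is locked days over window days, a control for
  the mobility context of the study year.

## Spatial autocorrelation

Weights are k-nearest-neighbor (k = 8 by default) on planar
coordinates, row-standardized, ties broken by unit order; rook
adjacency is available for raster fixtures. Global Moran's I uses the
standard cross-product form with a two-sided permutation p centered on
the null expectation −1/(n−1). LISA uses `I_i = z_i lag_i / (Σz²/n)`
with conditional (hold-one-out) permutation and classes HH/LL/HL/LH
gated at α = 0.05. With row-standardized weights the mean of the local
statistics equals the global statistic, which the tests assert exactly.
Under i.i.d. noise at α = 0.05 at least 90% of units must come out
not-significant.

## Models

**Modelling frame.** One row per community: the emotion index (or, on
synthetic data, latent emotion), the 14 covariates, and planar
coordinates. Frames refuse missing cells by naming the offending
communities — silent imputation would undermine the locality logic
downstream.

**GWRF.** For each community, the `bandwidth` nearest communities (an
adaptive neighborhood; the distance to the farthest neighbor is the
bandwidth distance) are weighted by a bisquare kernel
`(1 - (d/d_max)^2)^2` and a random forest is fitted with those
observation weights. Kernel weights enter as `ranger` case weights
(weighted bootstrap), the most direct reading of "local calibration
through spatial weights". Predictions at a new point come from the
nearest fitted location's forest — no blending, so every prediction is
attributable to one local model. With a uniform kernel and
`bandwidth = n` every local forest sees all data unweighted, and the
model is *bit-identical* to the global forest under the same seed; this
is the oracle used to validate the implementation. The focal
observation's out-of-bag prediction is retained per location. Forest
defaults are 500 trees, unlimited depth, minimum leaf 3, `mtry = p/3`;
the heavier analyses in the acceptance script and tests use 300 trees
and bandwidth 60 on 300 communities, an explicit problem-size choice
that leaves all conclusions unchanged. Bandwidth can also be selected
by grid search on focal out-of-bag RMSE (`select_bandwidth()`); no
selection criterion is dictated by the study design, so none is run by
default.

**Benchmarks.** The global random forest is the aspatial reference.
GWR fits kernel-weighted least squares per location over the same
adaptive neighborhoods, with a tiny ridge fallback (1e-8 of the mean
weighted diagonal) for rank-deficient local designs; exactly linear
noiseless data must be recovered to numerical precision at any
bandwidth, and the uniform full-bandwidth limit is OLS.

**Evaluation.** R² = 1 − SSE/SST, MAE, RMSE. The three-model
comparison defaults to spatially blocked 5-fold cross-validation
(k-means clusters of coordinates as folds), because random folds leak
spatial structure into local models; in-sample and out-of-bag modes are
also available and always labeled in the output. GWR's "out-of-bag"
analogue refits each local model with the focal weight zeroed.

## Interpretation

**Shapley values.** The value function is interventional: `v(S)` is the
mean model output over a background sample with the factors outside `S`
replaced by background values. Exact enumeration (≤ 16 factors, used up
to ~10 in practice) satisfies efficiency, null player and symmetry
exactly and reproduces the analytic `phi = beta (x - x̄)` for linear
models; the permutation-sampling estimator is unbiased for the same
quantity, satisfies efficiency exactly by telescoping, and is compared
to exact enumeration within Monte-Carlo error in the tests. For global
importance the background is the full data (subsampled for
tractability); for local models it is the community's own neighborhood
— the model has never seen anything else.

**Dominant factors.** Per community, mean |phi| over (a subsample of)
its neighborhood observations under its local forest; the dominant
factor is the argmax, ties broken by configured factor order. All 14
factors compete, including controls. The defaults (32 permutations, 6
observations, 12 background rows per community) are sized for the
argmax decision, whose margins in practice are several-fold; raising
them changes runtime, not maps.

**PDPs and turning points.** `PDP(g)` is the mean prediction with one
factor pinned to `g` over a quantile grid (so the curve never
extrapolates). The dispersion band is the across-observation standard
deviation — deliberately *not* a confidence interval, which would
require a resampling scheme the study design does not specify. Turning
points are located as the interior extremum of the lightly smoothed
curve (window 3); a curve monotone after smoothing has no turning
point and returns NA.

**Local effect surfaces.** Per community, the least-squares slope of
the local PDP over the neighborhood's factor range, exported with its
sign for mapping. Communities without local variation in the factor are
flagged NA rather than silently zeroed.

## The synthetic city

The generator exists so that every stage above can be tested against
known truth. It emulates: clustered community placement (a Thomas-style
cluster process plus a uniform background, Voronoi polygons as
community footprints; centroids keep a minimum separation of 0.3× the
mean spacing, as real communities have minimum extents, so no footprint
degenerates into a sliver smaller than an analysis grid cell); log-normal populations floored at 500 so
standardization is always defined; 14 covariates, each a smooth random
spatial surface plus a *persistent* community-level deviation, with
greenness and lockdown also carrying deterministic seasonal shifts and
a small seasonal fluctuation. Persistence matters: a community's
vegetation anomaly does not resample every season, and without that
persistence season-averaged covariates would decouple from the annual
signal by construction (an errors-in-variables artifact, not a feature
of the method).

Latent negative emotion is additive in piecewise-linear factor effects
with region and season modulation plus homoscedastic Gaussian noise
(`noise_sd`, default 0.08). The default effect specification encodes
the structures the pipeline is designed to detect, at magnitudes chosen
to be realistic rather than overwhelming (active-factor contributions
of ~0.1–0.3 SD each against 0.08 noise):

* `ndvi`: V-shaped with a direction reversal at 0.5, strongest in
  spring, weakest in winter, salient in region 1 and muted in region 2;
* `access_green`: linear with a *sign flip* between regions (protective
  in region 1, adverse in region 2), dominating region 2;
* `lpi`: bends from positive to negative at 40%;
* `openness` (mildly protective) and `lockdown` (adverse) linear terms;
* the remaining nine factors are inert nuisance covariates.

Post counts are Poisson with intensity proportional to population *and*
to polygon area (geotagged activity accrues over both residents and
places); this also makes the KDE-then-standardize indicator
identifiable for latent emotion, which is precisely the property the
real pipeline assumes of check-in data. Post locations are uniform
within polygons — the within-community distribution of real check-ins
is unknown, and this is a deliberate modelling choice, not an inference.
Sentiment labels are Bernoulli(negative) through a logistic link in
latent emotion, remaining posts split evenly positive/neutral.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: street networks and realistic routing,
posting-behavior demographics, text content, spatially correlated
noise, temporal autocorrelation within seasons, and measurement error
in the covariates.

"Off the region boundary" in recovery checks means communities whose
centroid is more than 1,500 m from the effect-region bisector (half the
default bandwidth distance scale), so local neighborhoods are not
forced to straddle regimes.

## Numerical choices and degenerate inputs

* KDE accumulates per event over its kernel support window; the
  Gaussian kernel is truncated at 6 bandwidths (relative tail mass
  < 1e-8).
* kNN ties, including duplicate coordinates, break by unit order, with
  a warning for duplicates.
* Zero-variance responses: Moran's I and R² refuse (undefined); the
  global forest warns and fits the constant.
* Permutation p-values use the (count + 1)/(n + 1) convention and are
  reproducible under stored seeds.
* All stage seeds derive deterministically from one master seed, and
  the whole pipeline is byte-identical across reruns with the same
  configuration — checked file by file in the tests.

## Problem sizes used in checks

The default study conditions are 300 communities on a 30 km × 30 km
extent, four seasons, ~50 posts per community-season. The acceptance
analyses use 300-tree forests with a 60-neighbor bandwidth; the
determinism check runs the full pipeline twice at 60 communities; unit
tests use 20–60-community cities. These sizes were chosen so the whole
suite completes comfortably on a single CPU while leaving every
qualitative conclusion unchanged at larger settings.

## Known limitations

GWRF local forests share one seed across locations (required for the
global-limit identity); consequences for between-location correlation
of Monte-Carlo noise are negligible at 300+ trees. Prediction routes to
the single nearest local model, so predicted surfaces are piecewise
with Voronoi seams; a blending flag would trade auditability for
smoothness and is deliberately not the default. The Shapley value
function is interventional; tree-path-conditional variants would give
different attributions for correlated factors. The indicator inherits
KDE edge bias near the extent boundary; mass lost outside the grid is
not folded back.
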