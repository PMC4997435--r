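---
title: "Space-time interpolation by the extension approach: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time interpolation by the extension approach: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stfield)
```

## The problem and the model

Exposure assessment needs a pollutant concentration at places and days
where nothing was measured: monitoring networks are sparse in space
and gappy in time, while health analyses want a daily value at every
census-unit centroid. stfield implements two deterministic
interpolants that treat the two dimensions of space and the one of
time *simultaneously*, by the extension approach: a time scale
$c$ (spatial-distance units per day) embeds each observation
$(x, y, t, w)$ at the 3D point $(x, y, ct)$, and spatiotemporal
interpolation becomes ordinary 3D spatial interpolation.

The factor $c$ is the crux. It fixes the exchange rate between a day
and a degree: with $c = 1/5$, observations three days apart are as
"far" from each other as stations 0.6 degrees apart. There is no a
priori correct value — it is a property of the process being
interpolated — so the package ships the four conventional presets
($c = 1, 1/10, 1/5, 1/15$; `time_scale_presets()`) and selects among
them (or any user-supplied values) by cross-validation.

### Shape functions

`build_mesh()` Delaunay-tetrahedralizes the scaled cloud once per time
scale — one global mesh over the whole year, not per-day slices, so
tetrahedra freely connect observations across neighbouring days. For
a query inside a tetrahedron with vertex values $w_1, \dots, w_4$,

$$w(x,y,ct) = \sum_{i=1}^4 N_i(x,y,ct)\, w_i, \qquad N_i = V_i / V,$$

where $V_i$ is the volume of the sub-tetrahedron obtained by replacing
vertex $i$ with the query and $V$ the full volume: the linear
finite-element basis. The $N_i$ sum to one, are non-negative inside,
reach $N_i = 1$ at vertex $i$, and reproduce any field that is affine
in $(x, y, ct)$ exactly. Interpolation cost is constant per query
after point location, which the package does by walking the mesh's
face-neighbour graph (queries are processed in sorted order so
consecutive walks are short).

### Inverse distance weighting

The IDW variant replaces mesh geometry with the $N$ nearest samples
under the space-time metric
$d_i = \sqrt{(x_i-x)^2 + (y_i-y)^2 + c^2 (t_i-t)^2}$ and weights
$\lambda_i \propto (1/d_i)^p$. Both $N$ and the exponent $p$ matter:
small $N$ and large $p$ localize sharply (as $p \to \infty$ the result
is the nearest sample's value), large $N$ and small $p$ average widely
(as $p \to 0$, the plain mean of the $N$ neighbours). The default
search grid is $N \in \{3,\dots,7\}$, $p \in \{1.0, 1.5, \dots, 5.0\}$
— 45 configurations per time scale.

### Cross-validation and the five error statistics

`cross_validate()` randomly partitions the samples into $k$ near-equal
folds (default $k = 10$), interpolates each held-out fold from the
other $k-1$, and scores MAE, MSE, RMSE, MARE, and
$R^2_{CV} = \max(0,\, 1 - \mathrm{RMSE}^2/\mathrm{MSE}_{obs})$, a
coefficient of determination against the 1–1 line where
$\mathrm{MSE}_{obs}$ is the mean squared deviation of the held-out
observations from their own mean. Statistics are computed per fold and
averaged field-wise — note the averaged RMSE is the mean of per-fold
RMSEs, *not* the root of the averaged MSE. MARE is the default
selection criterion: concentration errors matter relative to their
level, and MARE is the least outlier-sensitive of the five.

Design choices the protocol leaves open, and what this package does:

* **Scope of $\bar{O}$ in $R^2_{CV}$**: computed per fold from that
  fold's observations, which is the only choice consistent with
  averaging per-fold statistics. A fold with constant observations has
  $\mathrm{MSE}_{obs} = 0$; the statistic is then reported as 0 with a
  warning (1 if the predictions are also perfect).
* **Shared folds in `grid_search()`**: every configuration is evaluated
  on the same random partition, so ranking differences are
  configuration effects, not split noise. Rankings are therefore
  deterministic given the seed (default 20090101).
* **Held-out points outside the training hull** (shape-function method
  only): excluded from that fold's statistics and counted, rather than
  imputed; a fold entirely outside is an error.

## Exposure analysis

`interpolate_daily_grid()` evaluates the selected interpolant at every
(centroid, day), chunked over centroids so memory stays bounded.
`exposure_summary()` then computes per unit: the annual mean
(unweighted over available days), seasonal means with winter = January
+ February + December of the *same* calendar year (the convention for
a single-year study; not a DJF winter spanning two years), and two
exceedance flags with strict inequalities: any day > 35 µg/m³, and
annual mean > 15 µg/m³. The regulatory daily standard is formally a
3-year 98th-percentile design value; the operational single-year rule
used here is "at least one day above". Missing centroid-days (outside
the hull) are excluded from denominators and can never trigger a flag;
a unit with no available days is reported missing, never flagged.
`population_exposed()` totals flagged units and their populations per
rule, and errors if a flagged unit lacks a population record.

## Numerical choices

* **Planar coordinates.** Longitude/latitude enter Euclidean formulas
  directly, with no projection — a deliberate simplification (and a
  limitation: a degree of longitude shrinks with latitude). Distances
  are therefore "degree-equivalent" units.
* **Day index.** $t$ is the 1-based day of year (January 1 → 1); leap
  years run to 366.
* **Grid cosphericity and the joggle.** A monitoring data set is a
  sites × days grid in $(x, y, ct)$: any two sites on any two days form
  an exactly cocircular rectangle, so the Delaunay triangulation is
  degenerate almost everywhere. The mesher breaks these ties with a
  deterministic, reproducible perturbation of about $10^{-10}$ of the
  cloud extent (the same idea as qhull's "joggle"), and the perturbed
  coordinates *are* the stored mesh geometry, so every downstream
  weight is internally consistent. The cost is that "exact" properties
  (vertex reproduction, linear-field reproduction) hold to roughly
  $10^{-9}$ relative rather than to machine precision; the geometric
  predicates themselves use magnitude-scaled error bounds so the
  joggle is resolved reliably at every local scale.
* **Degenerate slivers.** Tetrahedra with volume ≤ `volume_tolerance`
  (default $10^{-12}$ scaled units³) are flagged; queries landing in
  one are resolved through a neighbouring tetrahedron.
* **Duplicate records** (same site, same day) are merged by arithmetic
  mean with a warning before meshing.
* **Outside-hull queries.** The convex hull of a monitoring network
  does not cover coastal or border centroids; by default such queries
  are missing, with optional nearest-vertex or meshless IDW fallbacks
  (`outside = "nearest"` / `"idw"`).
* **IDW ties and zero distances.** Neighbour ties are broken by
  ascending sample index (reproducibility); a query at distance zero
  returns the co-located measurement (their mean if several), the
  continuity limit of the weights. Weights are computed as
  $(d_{\min}/d_i)^p$, which is overflow-safe at large $p$.
* **Outlier rule.** Daily values strictly above 250 µg/m³ are treated
  as recording errors or extreme transients and removed before
  fitting; the boundary value 250 itself is kept.

## The synthetic generator

`field_spec()` defines a ground truth
$w^*(x,y,t) = \text{baseline} + \sum_j a_j e^{-d_j^2/2\ell_j^2} +
A \sin(2\pi (t-\phi)/365)$, floored at 0.1 µg/m³: Gaussian regional
hotspots over a smooth background plus one seasonal cycle. The
defaults emulate a contiguous-US PM2.5 year as a scientist would
sketch it: baseline 10 µg/m³; three hotspots (amplitudes 10, 8, 6
µg/m³ with 2–3 degree length scales, loosely a Central-Valley, a
northern-Rockies and an Appalachian feature); winter-peaking
seasonality of ±3 µg/m³; Gaussian noise of 3 µg/m³; 58 % of site-days
missing (the approximate gappiness of the real 955-site network); and
a $10^{-4}$ outlier rate with +300 µg/m³ excursions, matching the
16-in-146k prevalence of gross outliers. `generate_units()` draws
centroids in an interior margin of the domain with populations uniform
in 600–3000, the census block-group size band.

What the generator does *not* emulate: spatially correlated noise,
weather-driven synoptic events, preferential placement of monitors in
cities, or coastline-shaped domains. Passing the recovery tests
therefore demonstrates that the pipeline is correct and well
conditioned on smooth fields with realistic magnitudes — not that any
particular accuracy will be attained on real data.

## Problem sizes used by the test suite

The suite exercises meshes from 4 to ~73,000 vertices. The end-to-end
recovery test uses a dense 200-site × 365-day network with 1 µg/m³
noise and 500 centroids (an annual-mean MAE below 1 µg/m³ and ≥ 95 %
exceedance-flag agreement against the noiseless truth); the
model-selection test runs the full 4-scale × 45-configuration IDW grid
on a 50-site × 60-day set, twice, to confirm deterministic ranking.
These sizes keep the full suite under a couple of minutes on one CPU
while covering every code path at realistic densities.

## Known limitations

* Degrees are treated as planar; no geodesic or projected variant.
* Shape-function estimates are undefined outside the convex hull — the
  familiar coastal-stripe artifact; the IDW fallback is a pragmatic
  patch, not a boundary model.
* Both methods are deterministic: no prediction uncertainty is
  produced (contrast kriging).
* Only linear shape functions are implemented; no higher-order
  elements, no anisotropy beyond the single factor $c$, and no search
  radius or declustering for IDW.
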