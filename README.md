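# stfield

Deterministic spatiotemporal interpolation of daily pollutant
concentrations — written for exposure assessment studies that need a
concentration estimate at every census-unit centroid on every day of a
year, starting from a sparse monitoring network such as the EPA's PM2.5
sites.

## The method

Monitoring data are points (x, y, t, w): longitude, latitude, day index
and a daily concentration in µg/m³. Instead of interpolating each day's
map separately, time is treated as a third spatial dimension via the
**extension approach**: a time scale `c` (degrees per day) maps day `t`
to the coordinate `c·t`, and all interpolation happens in the 3D cloud
(x, y, c·t). The factor `c` controls how strongly yesterday's
measurement at a site competes with today's measurement at a
neighbouring site; it is a tunable of the method, selected by
cross-validation. Four canonical choices are provided as presets
(c = 1, 1/10, 1/5, 1/15).

Two interpolants are implemented on that cloud:

* **Shape functions (SF)** — the point cloud is Delaunay-tetrahedralized
  once per time scale, and a query inside tetrahedron (w₁…w₄) gets

  w(x, y, ct) = N₁w₁ + N₂w₂ + N₃w₃ + N₄w₄,  Nᵢ = Vᵢ / V,

  where Vᵢ are the volumes of the four sub-tetrahedra cut off by the
  query and V the tetrahedron volume — the linear finite-element basis,
  evaluated in O(1) per query after point location. The interpolant is
  continuous, reproduces the measurements, and is exact for fields that
  are linear in (x, y, ct).

* **IDW (Shepard's method)** — the N nearest samples under the space-time
  distance dᵢ = √((xᵢ−x)² + (yᵢ−y)² + c²(tᵢ−t)²) are averaged with
  weights λᵢ ∝ (1/dᵢ)ᵖ. The default search grid is N ∈ {3…7},
  p ∈ {1.0, 1.5, …, 5.0}.

Model selection uses **k-fold cross-validation** (default k = 10): each
fold is held out, the interpolant fitted on the rest, and the held-out
points scored by MAE, MSE, RMSE, MARE and R²_CV = max(0, 1 −
RMSE²/MSE_obs), the coefficient of determination against the 1–1 line;
per-fold statistics are averaged. `grid_search()` runs every candidate
configuration on one shared fold assignment and ranks by the statistic
you care about (MARE by default, the most robust of the five for
concentration data).

Downstream, `interpolate_daily_grid()` evaluates the chosen interpolant
at every (centroid, day), and `exposure_summary()` reduces that to
annual and seasonal means (winter = Jan + Feb + Dec of the same year),
flags units exceeding the air-quality standards (> 35 µg/m³ on any day;
annual mean > 15 µg/m³, both strict), and `population_exposed()` counts
the affected units and population.

A synthetic-data module (`field_spec()`, `generate_network()`,
`generate_units()`, `true_exposure()`) generates monitoring networks
with a known smooth ground truth — Gaussian regional hotspots plus a
seasonal sinusoid, measurement noise, missing site-days and rare gross
outliers (> 250 µg/m³, removed by `remove_outliers()` exactly as a real
pipeline would) — so the whole chain is testable without any download.

## Worked example

```r
library(stfield)

spec  <- field_spec(noise_sd = 2, seed = 42)
net   <- generate_network(spec, n_sites = 60, days = 120, missing_rate = 0.3)
units <- generate_units(spec, n_units = 40)

gs <- grid_search(net$samples, "sf", scales = time_scale_presets(),
                  criterion = "mare", k = 5)
gs$table[, c("scale_label", "c", "mae", "rmse", "mare", "r2cv")]
#>   scale_label      c  mae rmse  mare   r2cv
#> 1     Scale B 0.1000 2.07 4.75 0.175 0.0629
#> 2     Scale A 1.0000 2.07 4.66 0.176 0.0537
#> 3     Scale C 0.2000 2.09 5.07 0.178 0.0472
#> 4     Scale D 0.0667 2.10 5.07 0.178 0.0458
```

Every row is one time scale cross-validated on the same folds: with
this network, Scale B (c = 1/10) gives the lowest mean absolute
relative error (17.5 %) and the best R²_CV. The same search over IDW
configurations (`grid_search(..., "idw")`) lets you compare the two
methods on equal footing before committing to one.

```r
daily <- interpolate_daily_grid(net$samples, units, "sf",
                                time_scale(1/5), days = 1:120)
#> 2 of 4800 centroid-days outside the mesh hull left missing
summ <- exposure_summary(daily, year = 2009,
                         populations = units[, c("unit_id", "population")])
head(summ[, c("unit_id", "annual_mean", "winter", "days_available",
              "exceeds_annual")], 3)
#>   unit_id annual_mean   winter days_available exceeds_annual
#> 1  u00001    11.84428 12.82455            120          FALSE
#> 2  u00002    14.43386 14.67563            120          FALSE
#> 3  u00003    12.84400 13.93068            120          FALSE
unlist(population_exposed(summ, units))
#>  units_daily    pop_daily units_annual   pop_annual
#>            4         7877            3         6477
```

The mean over the first 120 days is ~12 µg/m³ away from the hotspots;
three units sit close enough to one to push their mean over the
15 µg/m³ annual standard, and their combined population (6,477 people
here) is what the exposure analysis reports.

A command-line wrapper over the same functions ships in
`inst/cli/stfield.R` with subcommands `simulate`, `interpolate`, `cv`,
`gridsearch` and `exposure`.

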