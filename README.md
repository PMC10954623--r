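# geoepi

Spatial clustering and hospital-proximity analysis for sentinel
surveillance case data.

Sentinel surveillance reports a disease only from a fixed hospital
network, so the map of reported cases confounds disease occurrence with
care access. `geoepi` implements the point-pattern toolkit used to read
such maps for hospital-reported pediatric intussusception and similar
acute conditions:

* **Average nearest-neighbor index** against complete spatial randomness:
  `NNI = D̄_obs / D̄_exp` with `D̄_exp = 0.5/√(n/A)`,
  `se = 0.26136/√(n²/A)`; NNI < 1 indicates clustering.
* **Global Moran's I** on collision-snapped per-location case counts
  `x_i`: `I = (n/S0) Σ_ij w_ij (x_i−x̄)(x_j−x̄) / Σ_i (x_i−x̄)²`, with
  analytical inference under the randomization and normality assumptions
  and a seeded permutation test.
* **Getis-Ord Gi\*** local hotspot detection with self-inclusive
  inverse-distance weights, 90/95/99% confidence classes, optional
  Benjamini-Hochberg FDR control, and admin-level hotspot tallies.
* **IDW interpolation** of the Gi* z-scores onto a raster surface
  (weighted-average, hence bounded by the data range), exported as an
  ESRI ASCII grid.
* **Proximity analysis**: episode-by-hospital great-circle distance
  matrices (haversine, R = 6371.0088 km), five half-open distance bands
  ([0,10), [10,50), [50,100), [100,250), [250,∞) km), district
  contiguity classification (same / adjacent / far), and region-level
  tables with published-table rounding conventions.
* **A synthetic line-list generator** with exponential distance-decay
  accrual around a 23-site, four-region sentinel network and per-episode
  ground truth, for calibration and recovery testing.

Readers and writers cover delimited case/hospital/adjacency tables (DMS
or decimal coordinates), GeoJSON (RFC 7946, lon-lat order) and ESRI
ASCII grids. Rows failing validation are collected into a rejection
report, never silently dropped.

## Worked example

```r
library(geoepi)

cfg <- sim_config(seed = 1, n_children = 800)   # defaults: sigma = 45 km,
sim <- generate_cases(cfg)                      # 23-site network, 66% male
a <- run_analyze(sim$cases, sim$hospitals, sim$adjacency,
                 analysis_params(n_perm = 199, seed = 1))
print(a)
```

```
geoepi analysis of 820 episodes / 599 snapped locations
NNI = 0.257 (observed 12.615 km / expected 49.116 km, n = 820, A = 7912619.9 km2)
z = -40.71, p = 0 [bounding_rectangle]
Moran's I = 0.3128 (E[I] = -0.0017)
z = 34.38, p = 4.72e-259 (randomization variance 8.37e-05)
permutation p = 0.005 (199 permutations)
Gi* classes:
         cold99          cold95          cold90 not_significant           hot90
              0               0               0             442               9
          hot95           hot99
             20             123
Mean treating-hospital distance 44.9 km; 67.1% < 50 km
```

Reading this output: 820 hospitalization episodes collapse to 599
weighted locations after 5-km collision snapping. NNI = 0.257 with
z = −40.7 says the residences are far more tightly packed than a random
scatter over the study window — the expected nearest-neighbor spacing
under randomness is 49 km, the observed is 12.6 km. Moran's I = 0.31
(z = 34, permutation p at its floor) says the per-location case counts
are positively autocorrelated: high-count locations neighbor high-count
locations. 143 locations reach 95% hotspot confidence or better, and
two-thirds of families live within 50 km of the treating hospital —
exactly the distance-decay referral structure the generator planted.

The proximity tables mirror surveillance reporting:

```r
print(a$band_table)
#> Episodes by region and distance band (n = 820 )
#>       <10 km 10-50 km 50-100 km 100-250 km >250 km total
#> East      46      105        46         24       1   222
#> ...
#> Pooled: <10 km 169 (20.61%), 10-50 km 381 (46.46%), ...
```

`write_analysis(a, "results/")` serializes the bundle (results JSON,
classified GeoJSON, IDW grid, CSV tables); `run_report("results/")`
renders a markdown summary. A thin shell wrapper lives at
`inst/exec/geoepi` (`geoepi simulate | analyze | report`).

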