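---
title: "Methods: spatial clustering and hospital proximity analysis of sentinel surveillance case data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial clustering and hospital proximity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoepi)
```

## The problem

Sentinel surveillance reports a disease only from a fixed network of
hospitals. For an acute pediatric emergency such as intussusception —
where a child must reach a surgical facility quickly — the geography of
reported cases mixes two signals: where disease actually occurs, and where
families can get care. `geoepi` implements the point-pattern toolkit used
to disentangle these: global clustering tests on the case locations, local
hotspot detection on case density, a smooth interpolated hotspot surface,
and proximity analysis between residences and treating hospitals. It also
ships a synthetic line-list generator with known ground truth, because the
statistics can only be trusted after they demonstrably recover planted
structure.

All coordinates are decimal degrees (WGS84 is assumed — surveillance
line lists rarely state a datum); DMS strings exist only at the I/O
boundary. All distances are great-circle (haversine) on a sphere of radius
6371.0088 km, the IUGG mean Earth radius. Straight-line distance is used
deliberately: in settings without reliable road-network data it is an
accepted proxy for travel effort.

## Preprocessing: collision snapping

Episode coordinates are snapped into *weighted locations* before any
density-based statistic: each episode joins the first previously founded
location within the snap radius (default 5 km), otherwise it founds a new
location. The per-location episode count $x_i$ is the analysis variable.
Greedy first-founder snapping is deterministic in stable input order and
never moves a location once placed; a centroid-updating variant exists
behind `method = "centroid"` for users who prefer the merged location to
track its members. Snapping conserves episodes by construction
($\sum_i x_i$ equals the episode count), and the tests assert this for
arbitrary radii.

The 5 km default reflects the subdistrict as the primary analysis unit:
residence coordinates are frequently subdistrict-centroid proxies, so
points closer than a subdistrict's scale are not meaningfully distinct.
Source descriptions of this preprocessing step are ambiguous between a
5 km *diameter* and a 5 km *radius*; the package takes the radius reading
as the default and leaves it configurable.

## Spatial weights

Weights are inverse-distance with a hard cutoff:
$w_{ij} = d_{ij}^{-p}$ for $0 < d_{ij} \le r$, zero beyond, with $p = 1$
by default; $p = 0$ degrades to binary band weights. The cutoff is chosen
by an explicit connectivity scan (`iterative_distance_scan()`): the
smallest candidate radius at which at least 99% of locations have a
neighbor. The "moving window" procedures of desktop GIS tools are not
specified publicly; this rule is a documented, reproducible stand-in and
the full diagnostic table is always returned so the choice can be audited.

For Gi\* the diagonal must carry a self-weight. An inverse-distance kernel
is singular at zero distance, so the package uses $w_{ii} = \max_j w_{ij}$
(the row maximum — the self-neighborhood is at least as close as the
nearest neighbor), and $w_{ii} = 1$ for binary weights. Row
standardization divides each nonzero row by its sum, leaves isolated rows
zero (reporting the count), and clears the symmetry flag.

The aggregate sums $S_0 = \sum_{ij} w_{ij}$,
$S_1 = \tfrac12\sum_{ij}(w_{ij}+w_{ji})^2$ and
$S_2 = \sum_i (\sum_j w_{ij} + \sum_j w_{ji})^2$ are computed once on
construction and verified in the tests against brute-force $O(n^2)$
recomputation to $10^{-12}$.

## Global clustering

**Nearest-neighbor index.** With $n$ points on a study area of $A$ km²,
the observed mean nearest-neighbor distance $\bar D_{obs}$ is compared
with the CSR expectation $\bar D_{exp} = 0.5/\sqrt{n/A}$:
$$\mathrm{NNI} = \bar D_{obs} / \bar D_{exp}, \qquad
z = \frac{\bar D_{obs} - \bar D_{exp}}{0.26136/\sqrt{n^2/A}}.$$
NNI is computed on *episode* points, duplicates included: co-located
proxy cases are genuine mass at a location and legitimately drive
$\bar D_{obs}$ toward zero. Only a fully coincident point set is an error.
The study area matters as much as the points, so three conventions are
offered: the bounding rectangle of the points in a local azimuthal
equal-area projection (default, the common desktop-GIS convention), the
convex hull, or a user-supplied area. The equal-area projection is used
*only* for area measurement; nearest-neighbor distances remain
great-circle.

**Global Moran's I** on the snapped counts:
$$I = \frac{n}{S_0}\,
  \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2},
  \qquad E[I] = -\tfrac{1}{n-1}.$$
The analytical variance is computed under both the randomization
assumption (default for the z-score; uses the sample kurtosis $b_2$) and
the normality assumption, and both are reported. A permutation test
(`morans_i_permutation()`) is offered alongside:
$p = (1 + \#\{|I_{perm}-E[I]| \ge |I_{obs}-E[I]|\})/(1+n_{perm})$, with
values permuted over locations, deterministic given its seed. The
analytical formulas require $n \ge 4$; for smaller $n$ the statistic is
still returned with `NA` inference, which keeps textbook two-point
examples (antithetic values give $I = -1$) available.

**Calibration.** The tests verify that the permutation test's type-I
error at $\alpha = 0.05$ lies in $[0.03, 0.07]$ over 400 white-noise
replicates ($n = 50$, 999 permutations), and that CSR point sets
($n = 1000$ on a 100 km window) keep NNI within $[0.94, 1.06]$ in at
least 95% of 200 seeds. The small residual upward bias of NNI under CSR
(about +1% at this $n$) is the textbook edge effect of uncorrected
nearest-neighbor statistics; the acceptance band absorbs it.

## Local hotspots and the IDW surface

**Getis-Ord Gi\***, self-inclusive form, per location:
$$z_i = \frac{\sum_j w_{ij}x_j - \bar X W_i}
  {S\sqrt{\frac{n\sum_j w_{ij}^2 - W_i^2}{n-1}}},
  \quad \bar X = \frac{\sum x}{n},\;
  S = \sqrt{\frac{\sum x^2}{n} - \bar X^2},\; W_i = \sum_j w_{ij}.$$
Locations whose denominator degenerates (isolates with no weights) get
`NA` with a warning rather than a fabricated score. Classification bins
$|z|$ against 1.645/1.960/2.576 into 90/95/99% hot and cold classes.
Benjamini-Hochberg FDR control across the per-location p-values is
implemented but off by default — the conventional map products report
plain confidence bins — and when enabled it is never more liberal than
the plain bins.

**IDW interpolation** of the Gi\* z-scores builds the continuous hotspot
surface: each cell is the weighted average
$\sum z_i d_i^{-p} / \sum d_i^{-p}$ over its neighborhood, $p = 2$ and
$k = 12$ nearest locations by default (a radius rule is available). A
cell on a data point takes that value exactly; empty neighborhoods are
NODATA. Because the weights are a convex combination, the surface is
bounded by the data range — the tests assert this, and it is why an
observed surface range such as $[-0.88, 4.45]$ is a meaningful summary of
the underlying z-field. Cells are square in degrees because the ESRI
ASCII grid export format requires a single cell size; at Indian latitudes
a degree of longitude is ~10% shorter in km than a degree of latitude,
which distorts cell aspect on the ground but not the interpolated values.
The IDW power and neighborhood are not stated by the upstream desktop
tools' defaults in any citable way; $p = 2$, $k = 12$ are the package's
documented choices.

## Proximity analysis

`distance_matrix()` computes the full episode-by-hospital great-circle
matrix plus, per episode, the treating-hospital distance and the
nearest-hospital distance (bypass diagnostics). Distances are tabulated
into five bands. The conventional band labels ("<10", ">10–50", …,
">251 km") leave the boundary points and the 250–251 km sliver undefined;
the package adopts half-open contiguous bins $[0,10)$, $[10,50)$,
$[50,100)$, $[100,250)$, $[250,\infty)$ so that every distance is
classified exactly once, and keeps the conventional labels. Tabulation is
at the *episode* level (a child with two hospitalizations contributes
twice), matching how surveillance tables count.

Contiguity classification labels each episode `same_district`,
`adjacent_district` (via the adjacency table) or `far_district`; an
unknown district degrades to `far_district` with a warning rather than an
error, because adjacency tables are routinely incomplete. Region tables
report row percentages to one decimal and pooled percentages to two,
matching the precision conventions of published surveillance tables.
`summarize_distances()` reports mean and median separately (published
summaries sometimes blur the two for skewed travel distances) along with
min/max, quartiles and the shares within 50 and 100 km.

## The synthetic generator

`generate_cases()` emulates the structure of a national sentinel
network's line list. Per child: a hospital drawn proportional to accrual
weight $\omega_h$; a generating distance drawn $\mathrm{Exp}(\sigma)$; a
bearing uniform on $[0, 360)$; the residence placed by a spherical direct
geodesic step (same 6371.0088 km radius as the distance code, so the
planted distance is exactly recoverable). The treating hospital is the
generating hospital. A fraction of residences is snapped to subdistrict
centroid proxies (a 0.05° lattice, ~5.5 km cells), co-locating nearby
cases the way proxy geocoding does. Repeat-episode children duplicate
their residence under a new episode id. Each stage draws from its own
deterministically derived substream, so adding a stage never perturbs
earlier draws and everything is byte-reproducible from one seed.

Defaults are fixed at the study conditions the package is calibrated
against: 2221 children; repeat-episode probability 58/2221; male share
0.66; retrospective share 1566/2221; 23 hospitals in four regions (North
5, South 8, East 7, West 3; 14 public / 9 private) with accrual weights
placing ~37% of cases at the top site, ~70% at the top six, and regional
shares near South 51% / East 26% / North 17% / West 5%. The decay scale
defaults to $\sigma = 45$ km: an exponential with that scale puts ~67% of
residences within 50 km and has mean ~45 km, jointly consistent with the
reported two-thirds-within-50-km share and ~47 km mean travel distance.
The exponential is the simplest one-parameter monotone distance-decay
kernel, consistent with reported referral behavior (reporting probability
falling steeply beyond a few tens of km); it is a modeling choice, not an
estimate, and the kernel scale is a plain argument. District assignment
uses generating-distance thresholds (same district < 25 km, ring
"adjacent" districts to 75 km, beyond that a far district), a deliberately
stylized geometry standing in for real district polygons.

What the generator does *not* emulate: population-density-weighted
residence placement, competing non-network hospitals, road networks,
incidence denominators. Passing recovery tests therefore shows the
statistics detect the planted referral-distance structure — not that any
particular real-world dataset has that structure.

The hospital coordinates in `default_hospitals()` are synthetic points
inside plausible regional bounding boxes, not real facilities.

## Test and acceptance problem sizes

The suite exercises: oracle equivalence of Moran's I / Gi\* / the weight
sums against independent dense-loop implementations at $n \le 50$; null
calibration with 400 permutation replicates and 200 CSR seeds at
$n = 1000$; pattern recovery over 20 simulator seeds at 400 children with
$\sigma = 25$ km (a tighter kernel than the default, making the planted
hotspot unambiguous); and closed-form worked examples (the 10-km-square
NNI of 4.0, the two-point Moran antithesis, the exponential CDF at 50 km,
one meridian degree = 111.195 km). These sizes were chosen to make the
sampling distributions tight enough for the stated acceptance bands while
keeping the whole suite to a couple of minutes on one core.

## Known limitations

* Greedy founder snapping is order-dependent by design; a different input
  order can yield different (equally valid) locations. Sort the input if
  a canonical result is needed.
* The NNI area conventions can disagree materially on elongated point
  clouds; the result object always carries the area and method used.
* Gi\* p-values are asymptotic normal and the classification ignores
  spatial dependence between tests unless FDR mode is enabled.
* The connectivity-scan cutoff rule is a documented stand-in for
  unspecified proprietary "iterative distance" procedures.
* Percentages in the region tables are rounded at fixed precision for
  fidelity to published-table conventions; recompute from counts for
  downstream arithmetic.

## Command-line use

The package is function-first; `inst/exec/geoepi` is a thin Rscript
wrapper (`geoepi simulate | analyze | report`) over `run_simulate()`,
`run_analyze_dir()` and `run_report()` for shell pipelines. Every output
directory carries a `provenance.json` with the seed and a config
fingerprint, and reruns with the same seed are byte-identical.
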