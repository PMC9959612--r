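---
title: "Methods: spatial risk zoning for epidemic disasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial risk zoning for epidemic disasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`epirisk` assesses the spatial risk of person-to-person epidemic disasters
from the layout of a city alone: no case data enter the model. Five
indicators are computed per 1 km fishnet cell — population density, night
light, road closeness, road betweenness, and a functional mixed kernel
density of POIs — then normalized, combined with entropy-method weights,
classified into five grades by geometric intervals, and summarized as the
spatial structure of the first-level risk cells. This vignette documents the
model, its assumptions, every tunable that matters, and the design decisions
taken where the method leaves room.

All distances are planar meters. Real inputs must be in a projected metric
CRS; the synthetic generator works in abstract planar coordinates, because
the network distances and kernel radii are metric quantities.

## Road network centralities

The road network is a *segment* graph: each polyline is one segment, and
segments are adjacent when their endpoints snap to a common junction
(tolerance `snap_tol_m`, default 0.5 m for standalone use and 0.1 m in the
pipeline, where the generator emits exactly-noded geometry). Crossings
without a shared endpoint are deliberately **not** planarized — an overpass
should not connect to the road below it — and parallel duplicate segments
remain distinct.

Segment-to-segment distance is the least-cost route from midpoint to
midpoint: each terminal segment contributes half its own cost, interior
segments their full cost, plus the junction turn angles. Three cost modes
are supported:

* `metric` — meters of network length;
* `angular` — cumulative turn degrees (a proxy for cognitive route
  complexity);
* `hybrid` — `meters + angular_weight_m_per_deg × degrees`. The conversion
  factor defaults to 1 m/degree; the hybrid literature states no canonical
  value, so the factor is an explicit, documented tunable.

Closeness is `NQPD(x) = Σ_{y≠x, d(x,y)≤R} W(y)·P(y)/d(x,y)` with discrete
`P ≡ 1` inside the radius. The continuous variant (`P ∈ [0,1]` for segments
partially inside the radius) is intentionally not implemented: the
partial-overlap rule is underdetermined, and the discrete form is the one
that can be verified exactly against enumeration.

Betweenness is
`TPBt(x) = Σ_y Σ_{z∈R_y, z≠y} OD(y,z,x)·W(z)·P(z)/TotalWeight(y)`.
Conventions, each chosen to be symmetric and exactly testable:

* `OD` is 1 when `x` is strictly interior to the geodesic, 0.5 when `x` is
  `y` or `z`, 0 otherwise;
* equal-cost geodesics split `OD` equally (deterministic,
  order-independent);
* `TotalWeight(y)` includes `y` itself (configurable via
  `include_self_in_total`).

Implementation: shortest-path costs come from Dijkstra on the
segment-transition graph; geodesic multiplicities from a dynamic program
over nodes in distance order, with fixpoint iteration inside equal-distance
groups so that zero-cost transitions (collinear continuations in pure
angular mode) are counted correctly — zero-cost *cycles* cannot arise from
plane geometry. Equal-cost detection uses an absolute tolerance of
`1e-7 × (1 + max distance)`; generic (randomly placed) geometry has no
near-ties at that scale, and structured grids have exact ties far above it.
The test suite certifies both centralities against an independent
brute-force oracle (Floyd–Warshall distances plus exhaustive depth-first
geodesic enumeration) to `1e-9` on 50 random graphs across all modes and
radii.

The default analysis radius is infinite (a global analysis) under the
hybrid metric — the configuration used for a whole-city assessment;
finite radii give localized accessibility.

## Kernel density surfaces

Per POI category, the density at a cell center `s` is the quartic (biweight)
kernel sum `f(s) = Σ_i w_i · 3/(πr²) · (1 − d_i²/r²)²` for points within
`r`. The quartic kernel is the standard GIS choice: compactly supported, so
mass conservation is exact up to discretization (within 1 % at cell size
`r/10`, which is the default cell size for standalone use; the pipeline uses
a fixed 100 m KDE cell so all categories share one grid). Surfaces are
evaluated at cell centers, not cell-averaged.

The search radius defaults to the rule of thumb
`H = 0.9 · min(√(1/ln 2)·D_m, SD) · n^(−0.2)` with `D_m` the median and `SD`
the standard distance about the mean center. The printed form of this rule
is typographically ambiguous about the radical; the standard reading
(`√(1/ln 2)` multiplying `D_m`) is implemented. Degenerate inputs (fewer
than 2 points, or all points coincident) raise an error advising an explicit
bandwidth; in the pipeline a category with fewer than 2 POIs contributes a
zero surface, and a degenerate rule-of-thumb falls back to one tenth of the
extent.

The six category surfaces are blended cell-wise with weights from the
public-dependence survey: the weight of category `c` is the mean of its
subcategory Likert means divided by the sum of the six category averages.
Weights must sum to 1 exactly — `mixed_density()` refuses to renormalize
silently. The per-item *dependence index* is the linear rescale
`clip((mean − 3)/2, 0, 1)`, anchored so that "generally important" (3) maps
to 0 and "very important" (5) to 1; these anchors reproduce the reference
table to three decimals on 12 of its 13 rows, and the remaining row (a
printed 1.000 against a computed 0.981) is treated as a capping/printing
anomaly, which the clip reproduces at the top anchor only.

## Fishnet aggregation

The fishnet tiles the boundary's bounding box with `cell_size_m` squares
(default 1000 m), anchored at the lower-left corner of the bounding box (the
anchor is otherwise arbitrary and documented as such), and keeps cells whose
intersection with the boundary has positive area — computed by exact
Sutherland–Hodgman clipping, so cells merely touching the boundary line are
dropped. Attachment rules:

* **rasters** (population, night light): statistic over raster cells whose
  *centers* fall in the fishnet cell; nodata excluded. The default statistic
  is the mean (density semantics — cell values should not depend on how many
  raster cells happen to fall inside); `sum` is available where totals are
  wanted. Center-point inclusion makes `sum` exactly conservative.
* **lines** (closeness/betweenness): length-weighted mean of segment values
  over the clipped pieces inside the cell — invariant to splitting segments
  into collinear parts.
* **surfaces** (mixed density): same center-point mean as rasters.

Cells with no raster centers or no roads get the value 0 and are flagged in
an `"empty"` attribute rather than left missing, so the entropy step always
sees a complete matrix; at the default resolutions (100 m raster in 1000 m
cells) empty cells do not occur.

## Entropy weighting, classification, structure

All five indicators are treated as risk-increasing (positive orientation)
and min–max normalized to [0, 1]. The entropy weight of column `j` is
`D_j = (1 − E_j)/(k − Σ_j E_j)` with
`E_j = −(1/ln n) Σ_i p_ij ln p_ij`, `p_ij = x_ij / Σ_i x_ij` and
`0·ln 0 := 0`. No `+ε` shift is applied by default (an optional `epsilon`
argument exists); an all-zero column is assigned `E = 1` and weight 0; if
*every* column reaches maximal entropy the non-degenerate columns share the
weight equally (the formula's 0/0 limit).

Geometric-interval classification uses class widths in geometric progression
`w_m = w_1·g^(m−1)` spanning `[min, max]`,
`w_1 = (max − min)(g − 1)/(g^k − 1)`. The proprietary algorithm behind the
conventional GIS implementation is not published, so the common ratio `g` is
chosen here by a documented, testable stand-in: a search over a log-spaced
grid of 400 values in `[1/8, 8]` (always including `g = 1`, the
equal-interval limit) minimizing the variance of per-class counts, ties
broken toward the smallest `g`. The search depends only on value ranks and
the range, making classification invariant to affine rescaling of the
scores. Values on a break go to the riskier class; fewer than `k` distinct
values fall back to quantile breaks with a warning. Class 1 is the highest
risk.

The spatial structure labels the 8-connected components of class-1 cells
(diagonal adjacency is continuity at 1 km scale; 4-connectivity is a
config option): the largest component is the *main* area; components whose
principal-axis extent ratio is at least `belt_ratio = 4` with a major extent
of at least `belt_min_cells = 8` cells are *belts* (checked before the size
rule, so an elongated chain is a belt, not a secondary center); remaining
components of at least `secondary_min_cells = 5` cells are *secondary*
centers; the rest are *points*. The thresholds are configuration with these
defaults — the qualitative main/secondary/belt/point typology gives no
numeric cutoffs.

Validation assigns each site the class of its containing cell and reports
per-class counts plus the coverage fraction of classes 1–2.

## The synthetic city

The generator emulates the *structure* of the real inputs, not their street
realism: a connected grid of roads (pitch 500 m over a 6 × 6 km extent) plus
three axis-aligned arterials noded against the grid; hotspot centers placed
on arterials in the central 20–80 % of the extent with at least 2σ pairwise
separation; population (100 m cells) and night light (500 m cells) equal to
a base level plus isotropic Gaussian hotspot bumps, times mean-one lognormal
noise (`sdlog = 0.3`) — positive-valued, "high in the center, low in the
periphery"; POIs as a 70/30 mixture of Gaussian clusters at hotspots
(σ = 400 m) and uniform background, with category/subcategory proportions
taken from the bundled taxonomy counts; validation sites 85 % within 2σ of a
truth center, 15 % uniform; survey responses `1 + Binomial(4, (m−1)/4)` per
item, which matches the target mean in expectation and the reference
standard deviations closely. One seed drives all draws in a documented
order (roads, hotspots, population, light, POIs, sites, survey), making a
city byte-reproducible.

Default intensities were chosen once as realistic urban magnitudes:
background population 5 persons per 100 m cell (≈500/km²) against a hotspot
amplitude of 200 (≈20,000/km² at the peak), night-light base 2 against
amplitude 40. The planted truth centers are metadata only — no pipeline
stage reads them.

What passing tests on this city do **not** show: robustness to the shapes of
real road networks (curvature, one-way systems, multi-level junctions), to
POI misclassification, to census/raster registration error, or to survey
bias. The generator's Gaussian hotspots are also rotationally symmetric,
which real density fields are not.

## Problem sizes and budgets

The test suite certifies the oracle equivalence on graphs of up to ~15
segments (where exhaustive geodesic enumeration is exact and fast), KDE mass
conservation on 200 points, entropy weights on 100 random matrices, and the
end-to-end recovery study on 20 seeded default cities (36 fishnet cells,
~390 segments, 2000 POIs each) — sizes at which the whole suite runs in a
couple of minutes on one CPU while still exercising every stage at full
fidelity. The recovery study asserts that every planted hotspot's cell is
classified first-level risk in at least 90 % of runs and that mean site
coverage of classes 1–2 is at least 0.85 — the generator plants 85 % of
sites in hotspot footprints, so coverage at or above that level indicates
the map concentrates risk where the truth is.

## Known limitations

* No continuous-space `P(y)`, one-way restrictions, turn prohibitions or
  mode-specific weighting in the network model.
* No adaptive-bandwidth, network-constrained or barrier-aware KDE.
* The geometric-interval ratio search is a stand-in for an unpublished
  algorithm; with a forced `g` the break formula is exact.
* Entropy weights are data-driven and therefore dataset-specific: they
  should not be transported between cities.
* GeoTIFF is not read or written; rasters use the plain-text ESRI ASCII
  grid, and vector layers use GeoJSON.
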