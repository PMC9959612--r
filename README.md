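# epirisk

Quantitative spatial risk zoning for person-to-person epidemic disasters in
large cities.

## The problem

When a human-to-human epidemic (COVID-19, SARS, influenza) first emerges,
case data, pharmaceutical interventions and control policies are all absent —
yet the places where outbreaks will concentrate are largely predictable from
the built environment: where people live densely, where they gather at night,
which roads channel through-traffic, and where urban functions (catering,
shopping, transport, hospitals, schools) are mixed most intensely. `epirisk`
implements a reproducible pipeline that turns those spatial signals into a
five-grade epidemic-disaster risk map for planners and public-health
analysts, without requiring any case data.

## The method

Five indicators are computed and aggregated onto a regular 1 km fishnet:

1. **Population density** — mean of a ~100 m population raster per cell.
2. **Night light** — mean of a ~500 m night-light raster per cell.
3. **Road closeness (NQPD)** — for each road segment *x*,
   `NQPD(x) = Σ_{y : d(x,y) ≤ R} W(y) P(y) / d(x,y)`,
   where `d(x,y)` is the midpoint-to-midpoint network distance under a
   metric, angular (turn-degree) or hybrid cost, `R` the search radius, and
   `P(y) ∈ {0,1}` in the discrete analysis.
4. **Road betweenness (TPBt)** —
   `TPBt(x) = Σ_y Σ_{z ∈ R_y} OD(y,z,x) W(z) P(z) / TotalWeight(y)`,
   the weighted share of shortest inter-segment routes passing through *x*
   (OD = 1 interior, 0.5 at the route endpoints, equal-cost geodesics split
   equally).
5. **Functional mixed kernel density** — per POI category, a quartic-kernel
   density `f(s) = Σ_i w_i · 3/(πr²) · (1 − d_i²/r²)²` with the
   rule-of-thumb radius `H = 0.9 · min(√(1/ln 2)·D_m, SD) · n^(−0.2)`
   (`D_m` median distance, `SD` standard distance), blended across the six
   functional categories with weights derived from a Likert-5 public
   dependence survey (mean-of-means, normalized).

Per-cell indicators are min–max normalized, weighted by the **entropy
method** (`E_j = −(1/ln n) Σ_i p_ij ln p_ij`,
`D_j = (1 − E_j)/(k − Σ E_j)`), and summed into a composite score. The score
is cut into five grades by **geometric-interval classification** (class
widths in geometric progression, common ratio chosen to balance class
counts); class 1 is the highest risk. The connected components of class-1
cells are labelled as the city's epidemic-disaster spatial structure — one
*main* area, *secondary* centers, elongated *belts* and isolated *points* —
and the map is validated by overlaying known high-risk sites.

Because the original municipal inputs (population grids, night-light
imagery, OSM roads, commercial POI databases) are proprietary or bulky, the
package ships a seeded **synthetic city generator** with planted hotspots so
that every stage — and the pipeline's ability to recover known risk centers —
is testable at desk scale.

## Worked example

```r
library(epirisk)

cfg <- synthetic_city_config(seed = 7)   # 6 x 6 km city, 3 planted hotspots
res <- run_pipeline(cfg)
res
#> <risk_assessment>
#>   seed 7; 36 fishnet cells; 391 road segments; 2000 POIs
#>   entropy weights:
#>     pop   light    nqpd    tpbt mixdens
#>  0.3343  0.3213  0.0384  0.0565  0.2495
#> <spatial_structure> main: 1, secondary: 0, belt: 0, point: 1
#>   site coverage in classes 1-2: 0.870

res$riskmap
#> <risk_map> 36 cells in 5 classes (1 = highest risk)
#> risk_class
#>  1  2  3  4  5
#>  5  6 12  9  4

round(res$category_weights, 3)
#> commercial green_space industrial public_service residential traffic
#>      0.173       0.167      0.164          0.164       0.130   0.203
```

Reading the output: the entropy weights say that in this synthetic city the
population raster (0.334), night light (0.321) and the functional mixed
density (0.250) are the most dispersed — hence most informative — indicators,
while the road centralities contribute less. Five of the 36 km² cells are
first-level risk; they contain all three planted hotspot centers, and 87 of
the 100 validation sites fall in the two highest grades. The survey-derived
category weights rank traffic (0.203) and commercial (0.173) functions as
the strongest crowd attractors, matching the reference survey's ordering.

All artifacts of a run (GeoJSON roads/POIs/risk map, ASCII-grid rasters, CSV
tables, a plain-text report) can be written with
`write_assessment(res, "out/")`, and a run can equally be driven from a YAML
configuration file: `run_pipeline("run.yaml")`.

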