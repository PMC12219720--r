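---
title: "Methods: VORS ecosystem health assessment and level-type zoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VORS ecosystem health assessment and level-type zoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorshealth)
```

This vignette records the model, its assumptions, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data tests do
and do not establish. Nothing here states an empirical result that the test
suite or the acceptance script does not itself compute.

## The composite model

The package assesses ecosystem health on a square tessellation (default
3 × 3 km units over 1 km cells) of a multi-temporal land-cover/NDVI raster
stack with six cover classes (1 farmland, 2 forestland, 3 grassland,
4 water, 5 construction, 6 bare land — this ordering is fixed throughout).

Per unit and year:

* **Vigour** `EV` — min–max normalised mean NDVI. NDVI is a standard proxy
  for primary productivity; the assumption is that greener units are more
  vigorous, which fails over open water and dense built-up areas — there the
  service and resilience components carry the signal instead.
* **Organisation** `EO` — a weighted sum of eight normalised landscape
  metrics computed *per unit window in isolation* (no cross-unit adjacency,
  matching per-unit partition statistics): Shannon diversity (SHDI),
  area-weighted mean patch fractal dimension (AWMPFD), patch density (FI1),
  contagion (CONTAG), and the water/forest restrictions of patch density and
  cohesion. Weights default to
  `0.25, 0.10, 0.25, 0.10, 0.10, 0.05, 0.10, 0.05` (grouped as
  0.35 LH + 0.35 LC + 0.30 IPC); they sum to 1 and are configurable.
* **Resilience** `ER` — `0.4 Σ A_i C_resist,i + 0.6 Σ A_i C_resil,i` over
  class shares `A_i`. The coefficient table is a required configuration
  input; the packaged default (forest 0.9/0.8, water 0.8/0.7, grassland
  0.7/0.7, farmland 0.5/0.6, bare 0.3/0.3, construction 0.2/0.2) encodes the
  usual ecological ordering and is clearly a default, not a measurement. All
  structural tests are coefficient-agnostic.
* **Natural health** `PH = (EV·EO·ER)^{1/3}` and **overall health**
  `HI = sqrt(PH·CESI)` — geometric means, so any zero component zeroes the
  composite (tested as an invariant).
* **Service** `ESV = Σ U_i VC_i`, `AESV = ESV / Σ U_i`,
  `CESI = (AESV − min) / (max − min)`. The value-coefficient table `VC` is
  likewise a config input with an illustrative default
  (water ≫ forest > grassland > farmland > bare > construction = 0); CESI is
  invariant to any positive rescaling of the whole table, and the tests
  exploit exactly that invariance.

### Metric definitions and directions

The source framework names the eight organisation metrics but does not
define them; this package follows the FRAGSTATS definitions, which are the
de-facto standard in the cited landscape-ecology literature. Three
consequences worth recording:

* **Fragmentation index**: operationalised as patch density (patches per
  km²) — the most common reading; FI1 over all classes, FI2/FI3 restricted
  to water/forest patches with the *total* unit area in the denominator.
* **Direction of normalisation**: fragmentation is ecologically "higher =
  worse organisation", so FI1/FI2/FI3 are inverted during min–max
  normalisation; the other five metrics enter positively. The direction is
  unstated in the source and is therefore a package decision, switchable in
  the code path that builds `EO`.
* **CONTAG conventions**: single-class (or single-cell) windows return 100
  (maximal aggregation); a two-class checkerboard gives exactly 50 under the
  formula (only unlike adjacencies), and the formula's minimum of 0 requires
  an equal like/unlike adjacency mix — both covered by analytic tests.
  AWMPFD's single-cell patches (`log a = 0`) contribute the geometric lower
  bound 1.0.

### Normalisation domain

Whether indices are normalised per year or pooled across years is unstated
in the source. The default is **pooled**: with per-year normalisation every
year spans [0, 1] by construction and yearly means cannot be compared,
whereas the source compares yearly means. A `per-year` switch exists. EV,
EO (via its metrics), ER and CESI are each normalised separately; PH and HI
are not re-normalised.

### Levels and classification

Five levels (low … excellent) by exact Fisher–Jenks natural breaks on the
pooled HI values; intervals are right-closed with the lowest class closed at
the minimum. The published fixed HI bounds (0.174/0.254/0.324/0.493) are
available as `reference_hi_breaks()` and as the `level_method = "fixed"`
config switch. The published CESI level bounds repeat the PH bounds verbatim
(an apparent typesetting slip), so CESI levels are never taken from that
sentence — natural breaks are used wherever CESI classes are needed.

The Jenks solver is an exact weighted dynamic program over distinct values.
Above 4096 distinct values the input is first reduced to 4096 quantile bins
(bin mean as representative, count as weight); the solution is then exact
for the binned problem. This keeps pipeline-scale classification (22k+
values) inside a second while the oracle tests exercise the exact path.

## Spatial statistics

Queen contiguity on the unit lattice with row-standardisation is the default
for Moran's I (binary + self-inclusion for Gi*), because the source names
the tests but not the weights — its printed I values are therefore not
exactly recomputable even with the real data, and no test targets them.
Moran's I uses the analytic randomisation-assumption variance for z and a
two-sided normal p, with an optional seeded permutation p. Gi* uses the
standard self-inclusive formulation with the population SD. Hot/cold tiers
at |z| ≥ 1.65/1.96/2.58; no multiple-testing correction by default (matching
the common three-tier mapping practice), units missing from the data are
dropped from the weights rather than imputed.

## Geodetector

`q = 1 − Σ_h N_h σ²_h / (N σ²)` with population variances; the p-value uses
the noncentral-F transformation of q from the original derivation, with a
seeded permutation fallback. Drivers are discretised by Jenks with k = 5 by
default (k and method configurable per run); 5 matches the five-level
conventions used everywhere else. Interaction detection computes q on the
cross-product stratification and classifies the triple (q1, q2, q12) with an
ordered rule chain — independence within tol, then nonlinear enhancement,
dual-factor enhancement, nonlinear attenuation, else single-factor nonlinear
attenuation — which is mutually exclusive and exhaustive by construction;
`tol = 1e-6` on the q scale because exact equality of floating-point q sums
essentially never occurs. Boundary ties resolve toward the weaker claim.

## Change typing and zoning

Per-unit level trajectories are typed by the ΔL/S_L predicates (continuous
decline, fluctuating decline, stable, fluctuating rise, continuous rise).
Mixed-sign trajectories with S_L = 0 match none of the published predicates;
they are typed **stable** (S_L = 0 is the stable signature) and flagged
`fluctuating_neutral` — the "gap rule". Exhaustive enumeration of all 5^5
five-timepoint trajectories (an acceptance criterion) shows the predicates
plus the gap rule assign exactly one type each.

County zoning crosses the current level class (Ia best … Va worst, from
area-weighted mean HI classed by natural breaks over the pooled county-year
scores — pooling makes county levels comparable over time, which the
trajectory typing requires) with the change-type class. The type coding is
**reversed** relative to the change-type numbering: Ib = continuous rise …
Vb = continuous decline. Rationale: the published zone table pairs low
health with IVb/Vb under the caption "continuous decline", which contradicts
the change-type ordering unless the b-codes are reversed; with the reversal
every zone row matches its caption and exactly the printed 23 level–type
combinations emerge, leaving two natural gaps (Ia–Vb, Va–Ib) that are
assigned by nearest-caption fallback (sensitive monitoring / strict control)
and flagged in the output. The duplicated entries in the preventive row are
read as IIa–IIb / IIa–IIIb, the only reading that yields 23 distinct pairs
consistent with "high current health level". The lookup is a plain editable
table in the configuration.

County score aggregation uses the area-weighted mean of unit HI (weights =
valid cell counts); the aggregation statistic is unstated in the source, and
a majority-level alternative would be less sensitive to within-county
extremes but discards magnitude — the weighted mean was chosen and is
isolated behind `county_level_class()`.

## The synthetic world

The generator emulates the input stack at desk scale — 200 × 200 cells of
1 km, 3 km units (67 × 67 = 4489 units), T = 5, 64 counties — and is a pure
function of one master seed (expanded to per-component sub-seeds by a fixed
scheme, `sub_seed()`).

* **Land cover**: a latent Gaussian field (FFT-smoothed white noise, padded
  so there is no wrap-around correlation; range 8 cells by default)
  thresholded at the target-proportion quantiles. This gives controllable
  spatial autocorrelation *and* exact proportion control (to one cell) —
  the reason this construction was chosen over e.g. sequential simulation.
  Default proportions: farmland 0.32, forest 0.38, grassland 0.08, water
  0.12, construction 0.07, bare 0.03 — a forest/farmland-dominated
  lake-plain mix. Transitions apply a row-stochastic matrix (default: mild
  urban expansion, 2%/step farmland/grassland → construction) with
  destinations biased toward neighbourhoods already containing the target
  class, so construction grows around existing construction.
* **NDVI**: class mean + smooth noise (SD 0.08), clipped to [−1, 1]. Class
  means are deliberately compressed into [0.05, 0.55] so the planted-hotspot
  boost cannot clip at the ceiling.
* **Planted hotspot**: an 8 × 8 block of units whose NDVI cells are raised
  by 3 background SDs of the unit-mean NDVI (the stated detection regime).
  The Gi* sensitivity criterion (≥ 90% of planted units hot at 95%) is
  evaluated on unit-mean NDVI, the variable the hotspot is planted in.
* **Drivers**: each of X1..X9 is a stratum-mean surface plus within-stratum
  noise, with the noise *rescaled post hoc* so the Geodetector q of the
  driver against its own generating strata equals the designed value exactly
  — recovery tests are therefore deterministic at tolerance 1e-9 rather than
  Monte-Carlo. X8/X9 (population density, land urbanisation) take their
  strata from smoothed construction density, so they co-vary with
  urbanisation. Surfaces are affinely mapped to plausible physical ranges
  (q is affine-invariant).
* **Counties**: seeds drawn uniformly, then multi-source breadth-first
  growth on the 4-neighbour lattice (geodesic Voronoi). Euclidean lattice
  Voronoi can produce disconnected slivers in degenerate tie cases; BFS
  growth guarantees non-empty, connected counties and a full partition by
  construction, which the stated invariants require.

**What a green test establishes — and does not.** The synthetic world has
clean, gap-free, perfectly aligned grids, stationary isotropic fields,
memoryless transitions and exactly engineered driver structure. Green tests
establish that the *computational chain* is correct (against brute-force
oracles and analytic limits) and that parameters planted in the data are
recovered. They do not establish that real CLCD transition rates, MODIS NDVI
climatology, sensor noise, nodata geometry or real driver collinearity are
handled "correctly" — no claim of statistical realism is made, and the
source study's regional numbers are not reproduction targets.

## Numerical choices and degenerate inputs

* Min–max normalisation errors on a degenerate (constant) domain rather than
  guessing; pipeline inputs that can be constant in pathological configs
  should use the per-year/pooled switches deliberately.
* Majority zonal statistic breaks ties toward the lowest class code
  (documented, tested).
* Units with < 2 valid cells: CONTAG 100, COHESION 0 by convention; empty
  units are NA and flagged.
* Moran's I and Gi* refuse constant inputs (zero variance) instead of
  returning NaN; missing units are dropped from the weights.
* Partial edge units are retained with their true cell counts and areas (the
  source's unit count implies boundary clipping but no rule is given; the
  package's rule is "keep and weight by area").
* All file outputs are written at full precision; two runs of one config are
  byte-identical (acceptance criterion).

## Known limitations

* No GeoTIFF I/O in this environment — rasters use the ESRI ASCII grid
  format exclusively (exact round trip, tested).
* The per-unit metric engine assumes one land-cover grid per year and no
  on-the-fly resampling; stacks must be pre-aligned.
* The noncentral-F p-value for q loses numerical precision for very large
  noncentrality (it is numerically 0 there); the permutation fallback exists
  for small-sample inference.
* County change typing uses pooled county-score breaks; with very few
  counties and near-constant scores the Jenks requirement of 5 distinct
  values can fail — the error message says to pool more data or supply
  breaks.
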