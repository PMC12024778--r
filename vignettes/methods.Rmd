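---
title: "Methods: modelling weekly honey production potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling weekly honey production potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melliflow)
```

## The scoring model

`melliflow` estimates the *potential* honey production of the
landscape around an apiary, patch by patch and week by week. The unit
of scoring is the Land Use Unit (LUU): one contiguous patch carrying a
single land-use class (LUS). The model assumes:

* planar metric coordinates — all distances in metres, all areas
  derived from polygon geometry; geographic inputs must be projected
  first;
* one flowering calendar per taxon per season (phenophases are a
  species-level property, not a plot-level one);
* nectar supply proportional to cover — a taxon covering `Rt` percent
  of a patch supplies `Rt/100` of its per-hectare potential over that
  patch;
* attractiveness declining linearly with distance from the apiary,
  reaching zero at 10 km.

The weekly nectariferous potential of a taxon spreads its annual
potential `pnt` (kg/ha, taken from the melliferous-flora literature;
genus-level values are used where a species is unlisted, and taxa with
no value at either rank are excluded from scoring but retained in
richness summaries) uniformly over its `Sf` flowering weeks, weighted
by the flowering intensity `If`:

$$\mathrm{pnht}(t, w) = \frac{\mathrm{pnt}_t}{S_f(t)}\, I_f(t, w),
\qquad I_f \in \{0, 0.5, 1\}$$

with `If = 1` at full bloom, `0.5` in the early and late phases and
`0` outside the window. Two consequences are load-bearing and tested
as invariants: the season total per taxon never exceeds `pnt`
(equality iff every flowering week is full), and a taxon contributes
only in weeks where it flowers.

Each LUU is scored per week as

$$\mathrm{HPP} = \max\!\left(0,\, 1 - \frac{D}{10\,000}\right)
 \cdot S \cdot \sum_t \frac{R_t}{100}\,\mathrm{pnht}(t, w)$$

with `D` the Euclidean distance (m) from the LUU's area centroid
("centre of gravity"; LUUs may be non-convex) to the apiary and `S`
the LUU area in hectares. Three modelling choices deserve note:

* **Distance clamp.** The linear factor would go negative beyond
  10 km; it is clamped at zero. Within the 1.5 km foraging radius the
  package targets, the clamp is inert — it only guards degenerate
  inputs.
* **Cover as a fraction.** `Rt` is recorded in percent;
  dimensional analysis (ha × kg/ha = kg) requires it to enter as
  `Rt/100`.
* **Per-LUU, never per-LUS.** The score is evaluated on each
  contiguous patch separately; class-level series are sums of patch
  scores, so a class split into near and far patches is discounted
  correctly.

`compute_surface()` closes the bookkeeping in three directions —
per-LUU weekly values, per-LUS series (kg and kg/ha, the latter
dividing by the class's *total* area rather than only the contributing
patches), and cumulative per-taxon contributions — and the three
decompositions are required to agree to 1e-9 relative, which the test
suite enforces.

## Survey processing

Braun-Blanquet classes are converted to percent cover by the standard
band midpoints (`r` = 0.1, `+` = 0.5, `1` = 2.5, `2` = 15, `3` = 37.5,
`4` = 62.5, `5` = 87.5). The survey methodology cites the scale
without a numeric mapping; midpoints are the conventional
quantification and are fixed as this package's convention.

Where an LUU holds several plots, a taxon's `Rt` is the mean cover
over those plots *counting absences as zero* — the unbiased
patch-level estimate. Plot-less LUUs borrow the nearest plot (centroid
to plot distance). By default only plots on the same LUS are eligible:
borrowing across classes would graft, say, a forest community onto a
grassland patch. The unrestricted variant
(`same_lus_only = FALSE`) is provided because the field protocol this
mirrors says only "nearest observation point". Classes that are never
surveyed (habitation, non-maize cropfields) end with empty taxon sets
and zero HPP.

## Landscape structure metrics

Per LUS: patch count `ni`, mean patch area `Si = Σ aij / ni` (ha),
patch density `Dti = ni / A × 10^6` (patches per 100 ha, `A` in m²)
and mean Euclidean nearest-neighbour distance `ENNi`. Choices:

* `dij` is **edge-to-edge** (minimum boundary distance), the Fragstats
  ENN definition, not centroid-to-centroid. For disjoint polygons the
  minimum lies at a vertex of one polygon against an edge of the
  other, so the implementation sweeps vertex-to-segment distances both
  ways, with a bounding-box lower bound to skip far pairs; tests
  compare it against an exhaustive all-segment-pairs oracle.
* Standard deviations are sample SDs (n − 1), the ecological-reporting
  norm; a single patch reports SD 0, and `ENNi` with fewer than two
  patches is `NA` with a warning (Fragstats behaviour).
* Adjacent same-class patches are **not dissolved**; counts reflect
  the map as drawn.

## The synthetic generator

No field data ship with the package, so `generator_config()` defaults
define the study conditions the pipeline emulates: a circular 707 ha
foraging area (1.5 km radius, apiary at the centre) with shares
forest 36.3 %, grassland 26.1 %, wasteland 9.06 %, riparian 1.71 %,
cropfield 4.17 %, maize 4.04 %, orchard 6.11 % and habitation as the
remainder (12.51 %), patch counts 40 / 114 / 38 / 13 / 43 / 49 / 132
per class, a 160-taxon pool, per-plot richness means
(forest 5.39, grassland 14.4, wasteland 5.78, riparian 16.7) and a
150 m systematic survey grid. Values not fixed by that description
were chosen once as field-realistic and are not tuned: 70 habitation
patches (≈1.26 ha village parcels), orchard and maize plot richness 5
and 3, community sizes proportional to the observed per-class species
totals, `pnt` drawn log-uniformly on 1–1000 kg/ha (published
potentials span orders of magnitude, from weak herbs to black locust),
10 % of taxa without a usable `pnt`, flowering onsets normally
distributed around a class-specific mean week (orchards earliest,
week 12; grasslands 19; maize 22) with 2–8-week windows, and a plot
retention of 0.54 — a 150 m grid over 707 ha yields ≈314 candidate
points and ≈262 after removing unsurveyed classes, while the emulated
protocol studied 142, i.e. roughly half of candidates were accessible
in the field.

The mosaic is built by tessellating the disc into ~6000 Voronoi cells
(`deldir`), then growing each patch as a connected set of cells:
large-patch classes claim space first, per-patch target areas are
drawn log-normally (CV ≈ 0.9) and normalised to the class share, and
growth stops when adding the next cell would overshoot more than
stopping. Leftover cells attach to the adjacent patch of the most
under-target class, which keeps realised shares within the ±2-point
tessellation tolerance while patch counts are exact by construction.
Riparian patches grow as elongated cell chains along a random stream
direction rather than as buffered polylines overlaid on the mosaic:
overlaying buffers would break the exact-tiling and non-overlap
invariants that every downstream computation relies on, while cell
chains keep corridor-shaped patches inside an exact tessellation.
A 1-week flowering window is a single *full* week and a 2-week window
is *early+late* — the simplest convention consistent with three
phenophases.

What the generator does **not** emulate: real parcel geometry
(Voronoi-grown patches are more isometric than ploughed fields),
spatial autocorrelation of communities between neighbouring plots,
inter-annual phenology shifts, weather, and any relationship between
`pnt` and phenology or habitat. Passing tests therefore demonstrate
the correctness and stability of the *computations* under realistic
statistical structure, not the ecological accuracy of any particular
map.

## Numerical choices

* Every polygon boolean operation during generation runs on one shared
  integer grid (1 µm resolution, origin 0) so that edges shared
  between neighbouring cells round identically; patches then tile with
  zero overlap and the summed patch area matches the configured total
  to 1e-6 relative.
* Polygon areas and centroids use the shoelace formula; rings are
  classified as holes by containment parity with a majority vote over
  decisive vertices, because touching rings share numerically
  perturbed boundary vertices.
* Point-in-polygon tests use even-odd parity with boundary points
  counted inside; rasterisation assigns each cell its centre's LUU and
  leaves cells outside every LUU as no-data.
* Taxon rankings break ties alphabetically (documented, deterministic).
* The degenerate Kruskal-Wallis case (all values identical in all
  groups) is reported as H = 0, p = 1. The two-by-two post-hoc is
  Dunn's z-test on pooled mean ranks with tie-corrected variance and
  Holm adjustment (Bonferroni available); the compact letter display
  assigns one letter per maximal clique of the non-significance graph,
  enumerated exactly.
* All randomness flows from a single integer seed; the survey stage
  derives its stream as seed + 1 so landscape and survey can be
  regenerated independently yet reproducibly.

## Problem sizes in the test suite

The suite exercises the full default mosaic (6000 cells, 499 patches,
~140 plots) once and reuses it across files; most tests run on a 40 ha
/ 14-patch fixture. Property suites use 100 random ≤20-patch
landscapes for the nearest-neighbour oracle, 200 random calendars for
the conservation law, 1000 null replicates for the type-I error of the
Kruskal-Wallis test, and 1000 random cells for the rasterisation
oracle.

## Known limitations

* HPP is a *potential*: no colony dynamics, recruitment, weather,
  competition between pollinators or realised-harvest calibration —
  couplings to colony models are natural extensions, not included.
* Maize contributes no nectar in this model (it matters for pollen,
  which is out of scope), and grasses are never part of survey
  records.
* The per-hectare series divides by the class's total area; dividing
  by contributing-patch area only would raise sparse classes.
* ENN values depend on patch geometry, which the generator only
  emulates statistically; structure metrics on synthetic mosaics are
  validated against oracles and configuration targets, not against any
  real map's ENN.
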