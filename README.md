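# melliflow

Space-and-time mapping of the honey production potential (HPP) of the
landscape around an apiary.

Beekeepers and landscape ecologists want to know not just *how much*
nectar a territory can offer a honeybee colony, but *where* and *in
which week*. `melliflow` scores every contiguous land-use patch (Land
Use Unit, LUU) of a foraging area for each week of the flowering
season, by combining four ingredients:

* a polygonal land-use map in planar metric coordinates, with eight
  land-use classes (LUS): forest, grassland, wasteland, riparian
  forest, arable crops excluding maize, maize, orchard,
  habitation/other;
* a botanical survey of circular observation plots (herb layer
  r = 0.56 m, shrub layer r = 4 m, tree layer r = 8 m) with
  Braun-Blanquet cover-abundance classes per taxon;
* per-taxon flowering calendars over ISO weeks 10–34, with three
  phenophases (early / full / late bloom);
* published annual nectariferous potentials `pnt` (kg/ha) per taxon.

## The model

The weekly nectariferous potential of taxon *t* spreads its annual
potential over its flowering window of `Sf` weeks, damped by the
flowering intensity `If` (0.5 in early and late bloom, 1 at full
bloom, 0 otherwise):

    pnht = pnt / Sf * If(week)            [kg/ha/week]

so a taxon's season total never exceeds `pnt`, with equality exactly
when every flowering week is at full bloom.

Each LUU is then scored per week as

    HPP = max(0, 1 - D/10000) * S * sum_t( Rt/100 * pnht )   [kg/week]

with `D` the distance (m) from the LUU centroid to the apiary, `S` the
LUU area (ha) and `Rt` the percent cover of taxon *t* on the LUU
(mean over the LUU's observation plots; plot-less LUUs borrow the
nearest plot of the same land-use class). The per-LUU scores aggregate
exactly into landscape weekly totals, per-LUS time series (kg and
kg/ha) and cumulative per-taxon contributions.

Around this core the package provides Fragstats-style landscape
structure metrics (mean patch area `Si`, patch density `Dti` per
100 ha, edge-to-edge Euclidean nearest-neighbour distance `ENNi`),
Kruskal-Wallis comparisons across land-use classes with Dunn post-hoc
letters, GeoJSON / CSV / ESRI-ASCII exports, and a fully seeded
synthetic generator that emulates a 707 ha heterogeneous mosaic
(Voronoi-cell tessellation grown into labelled patches, systematic
150 m survey grid, ~160-taxon pool with class-specific richness and
staggered phenology) so that the entire pipeline runs and is tested
without any field data.

## Worked example

```r
library(melliflow)

cfg <- generator_config()          # the 707 ha default mosaic
ls  <- generate_landscape(cfg)
sv  <- generate_survey(ls, cfg)

ls
#> landscape: 499 LUUs, 707 ha total
#>   apiary at (0, 0) m
#>   forest       40 patches   36.4%
#>   grassland   114 patches   26.1%
#>   ...

head(landscape_metrics(ls), 2)
#>         lus n_luu    Si_ha    Si_sd       Dti   ENNi_m  ENNi_sd share_pct
#> 1    forest    40 6.438152 5.032338  5.657709 36.83616 77.79482 36.425186
#> 2 grassland   114 1.619356 1.273656 16.124470 10.05754 26.67613 26.111260

surf <- hpp(ls, sv)
surf
#> hpp_surface: 499 LUUs x 25 weeks
#>   season total 55468.5 kg; peak week 21 (4669.1 kg)

summary(surf)
#> Weekly HPP by land-use class (kg), summed per period:
#>            p1_w10_15 p2_w16_19 p3_w20_27 p4_w28_34
#> forest        8881.1    4508.0    4952.8     421.2
#> grassland     5875.7    7349.7   15091.9     873.1
#> ...
```

The metrics table reads as: 40 forest patches average 6.44 ha
(5.66 per 100 ha of landscape) while 132 orchard patches average
0.33 ha — a fine-grained mosaic. The period table shows the seasonal
hand-over: forest carries the early season, grassland takes over from
mid-spring and dominates the late summer, and the season peaks in the
early-summer period (weeks 20–27).

Per-taxon diagnostics:

```r
rank_taxa(surf, 5)
#> taxon_001 taxon_160 taxon_028 taxon_045 taxon_055
#>    5455.5    4924.4    4323.7    4122.3    2909.1
round(lus_share_of_taxon(surf, "taxon_001"), 1)
#>     forest  grassland  wasteland   riparian  cropfield      maize
#>       74.6       25.1        0.0        0.0        0.0        0.0
#> ...
```

`run_pipeline(cfg, out_dir = "run1")` executes everything end to end
and writes the report bundle (metrics, richness and HPP tables as CSV,
weekly GeoJSON maps, group statistics, a config YAML and a manifest
with checksums and stage timings); reruns with the same seed are
reproducible file for file.

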