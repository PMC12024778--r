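Package: melliflow
Title: Space-and-Time Honey Production Potential of a Foraging Area
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the weekly honey production potential (HPP) of the
    landscape around an apiary. Combines landscape structure metrics
    (patch area, patch density, Euclidean nearest-neighbour distance),
    Braun-Blanquet vegetation surveys, per-taxon flowering phenology
    calendars and published nectariferous potentials into a
    distance-discounted, per-patch, per-week HPP score, with
    aggregations by land-use type and by taxon, Kruskal-Wallis group
    comparisons with Dunn post-hoc letters, and a seeded synthetic
    landscape generator for fully reproducible desk-scale analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deldir,
    sp,
    polyclip,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
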