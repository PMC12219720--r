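Package: vorshealth
Title: VORS Ecosystem Health Assessment and Level-Type Zoning on Gridded Land-Cover Data
Version: 0.1.0
Authors@R: person("VORS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Grid-based ecosystem health assessment for multi-temporal
    categorical land-cover and NDVI rasters. Computes per-unit composite
    health indices from the Vigour-Organisation-Resilience-Service (VORS)
    framework: NDVI-based vigour, an eight-metric landscape-organisation
    score (Shannon diversity, area-weighted fractal dimension, fragmentation,
    contagion, water/forest fragmentation and cohesion), land-cover-weighted
    resilience, and an equivalent-factor ecosystem-service value index.
    Includes exact Fisher-Jenks natural-breaks classification, global Moran's
    I and Getis-Ord Gi* hot/cold-spot mapping, Geodetector factor and
    interaction detection, temporal level-change typing, county-level
    control-zone assignment, and a fully seeded synthetic-scenario generator
    with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
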