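Package: firesmoke
Title: Global Landscape-Fire Air Pollution Exposure Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates daily fire-sourced PM2.5 and ozone concentrations on a
    fine latitude-longitude grid by downscaling coarse chemical-transport-model
    output with inverse-distance weighting, calibrating the downscaled fields
    against ground monitoring stations with random-forest regression, and
    attributing the fire-sourced share by ratio scaling of paired
    with-fire/without-fire simulations. Maps population exposure to substantial
    fire-sourced air pollution (SFAP) days via person-day, days-per-person,
    people-exposed and population-weighted-mean metrics over UN-adjusted
    population rasters, and provides the accompanying validation machinery:
    ordinary and spatial tenfold cross-validation, leave-one-cluster-out
    cross-validation over k-means station clusters, two-way fixed-effects
    within-R2, station-specific R2 summaries, a background-median smoke PM2.5
    observation operator, and per-grid linear trend tests. A seeded synthetic
    world generator with known plume footprints makes the full pipeline
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ranger,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
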