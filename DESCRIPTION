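Package: ugci
Title: Urban Green Carbon Index: Grid-Level Diagnosis and Prescription of
    Urban Green-Space Carbon Condition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the Urban Green Carbon Index (UGCI), an entropy-weighted
    composite of four grid-level carbon components (vegetation carbon storage,
    soil carbon storage, net carbon uptake, and soil carbon storage potential),
    and classifies grids into quartile-based management levels. For grids in
    poor condition it decomposes the index over the three most informative
    components on the ternary simplex and maps the limitation pattern to
    land-cover-specific management strategies. Includes closed-form carbon
    component models (IPCC-style stock equation with an urban correction
    factor, DBH allometry, a light-use-efficiency GPP model, ecosystem
    respiration, and annual NEP integration), patch and edge-effect landscape
    analytics (connected-component patches, 30 m edge rings, adjacency
    classes, zonal statistics, edge-versus-interior tests, patch-size
    correlation), and a seeded synthetic landscape generator so the full
    pipeline is testable without proprietary rasters. Rasters are exchanged as
    ESRI ASCII grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
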