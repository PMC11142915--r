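Package: borealshift
Title: Linking Current Boreal Forest Structure, Recent Canopy Cover Trends,
    and Climate-Driven Canopy Height Projections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for assessing the persistence of forest
    structure change across the North American boreal forest and the
    taiga-tundra ecotone. Provides quality filtering and maximum-aggregation
    gridding of spaceborne-lidar canopy height observations (ATL08-style
    RH98 segments), a 22-predictor bioclimatic random-forest canopy height
    model with permutation importance, pixel-wise GCM ensemble medians and
    future-minus-current difference maps across 4 SSPs and 4 twenty-year
    periods, per-pixel ordinary least squares trends in annual tree canopy
    cover, and landscape-scale zonal summaries feeding a 9-class taxonomy
    of recent-by-future structural change. A synthetic-data generator with
    known ground truth exercises every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
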