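Package: resilmob
Title: Community Resilience Metrics from Large-Scale Mobility Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures neighborhood-level disaster impact, recovery, and
    evacuation behavior from smartphone geolocation pings. Provides ping
    standardization and 1-km grid assignment, nighttime argmax inference of
    daily residence cells, baseline-relative activity deviation curves,
    Ward agglomerative clustering of neighborhood response trajectories,
    resilience-capacity metrics (impact magnitude, time-to-recovery, and
    signed area under the activity curve), spatiotemporal DBSCAN activity-area
    detection with hourly-profile typing for per-device home inference,
    origin-destination evacuation networks with destination tiers, and
    zone-to-cell damage apportionment for validation. A seeded synthetic city
    generator emulates the statistical structure of commercial ping panels so
    the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    geosphere,
    igraph,
    jsonlite,
    mgcv,
    pracma,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
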