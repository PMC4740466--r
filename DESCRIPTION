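Package: reefresidency
Title: Residency, Space Use and Partial Migration from Passive Acoustic
    Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing passive acoustic telemetry of reef-associated
    predators: reading and validating detection, receiver-deployment, tagging
    and environmental tables; daily presence under a two-detections-within-an-
    hour rule; residency and roaming indices with residency grouping;
    centre-of-activity positioning on a UTM plane with minimum linear
    dispersal; reef-to-reef movement matrices and shelf-position move
    frequencies; acoustic coverage estimates; multi-array migration-event
    detection with away/stay/return classification, travel-time and occupancy
    summaries; model-ready daily covariate tables; and a seeded detection-data
    simulator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
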