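Package: ternwinds
Title: Climate-Change Impacts Along the Arctic Tern Atlantic Flyway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess 21st-century climate-change impacts on the
    world's longest bird migration. Converts arctic tern tracking fixes into
    tern-day density surfaces, computes tern-density-weighted regional net
    primary production series from multi-model Earth-system ensembles with
    sensitive and conservative time-of-emergence signal-to-noise statistics,
    extracts the Southern Ocean sea-ice edge (15 percent concentration
    threshold) with monthly and decadal climatologies, builds seasonal wind
    climatologies by migration phase, and simulates wind-driven virtual tern
    ("vTern") northbound migrations with duration, land-crossing and
    occupancy summaries. A synthetic-climate generator (wind jets, NPP
    ensembles, seasonal sea ice, tracking fixes) makes the whole pipeline
    testable without external model output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
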