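Package: juristrack
Title: Jurisdictional Importance and Connectivity from Animal Tracking Data
Version: 0.9.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the year-round importance of national jurisdictions,
    the high seas, and regional fisheries management organisation (RFMO)
    competence areas to breeding populations of wide-ranging marine animals,
    chiefly seabirds tracked with GLS, PTT, or GPS devices. Tracks are
    standardised to one position per day, filtered, and truncated to a single
    breeding year; daily positions are assigned to maritime zones by
    point-in-polygon tests against a country/high-seas partition and an
    overlapping RFMO overlay; monthly zone occupancy is extrapolated to
    population-level time spent in bird-years; zone-level species richness,
    an equal-area hexagonal grid surface, and bipartite origin-country to
    zone connectivity networks are derived. A synthetic-world simulator with
    known ground-truth occupancy supports validation, including a
    geolocator-error sensitivity resampling procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
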