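Package: airside
Title: GPS Telemetry Analysis of Airside Wildlife Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing GPS-collar telemetry of mammals resident on
    airfields. Ingests Movebank-style fix tables with accuracy filtering and
    burn-in removal, detects interactions between movement steps and tarmacked
    airfield surfaces (runways, taxiways, connecting areas) by segment-polygon
    intersection, computes sunrise/sunset-anchored activity offsets with
    seasonal rank tests, daily and cumulative movement distances, and 95%
    kernel-utilisation-distribution home ranges with habitat composition.
    Includes a two-state correlated-random-walk simulator that generates
    synthetic airfields and collar datasets with ground-truth crossing logs
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
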