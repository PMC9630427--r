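Package: sightnet
Title: Protected-Area Use and Social Networks from Individual-ID Sighting Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses longitudinal individual-identification sighting tables
    from mark-resight studies of social mammals. Implements the
    between-sightings interval (BSI) as a proxy for protected-area use,
    male motivational-state strategy classification and male-week scoring,
    simple-ratio-index (SRI) association networks with Louvain community
    detection and reciprocal-majority dynamic community tracking across
    years, and a multiple-regression quadratic assignment procedure (MRQAP)
    relating social association to similarity in area use while controlling
    for spatial distance. A seeded fission-fusion sighting simulator with
    retained ground truth lets every stage run, and be validated, without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
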