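Package: diveTherm
Title: Reconstruction and Validation of Seawater Temperature Profiles from
    Satellite-Tag Dive Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning dive telemetry transmitted by Argos satellite
    tags on marine animals into quality-controlled vertical seawater
    temperature profiles, and for validating those profiles against a gridded
    ocean model product and against ARGO-style float profiles. Includes a
    decoder for a documented tag CSV dialect (retroactive time reconstruction
    from elapsed-time trailers, location-quality filtering, surfacing
    discard, temporal-coherence truncation), nearest-grid-cell collocation
    with average-then-interpolate vertical matching, stratified validation
    statistics (Pearson r, BIAS, RMSE, unbiased RMSE) by season, depth range
    and sub-region, an upper-ocean ARGO consistency check, and a synthetic
    ocean/telemetry generator with a known-truth thermocline field so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    data.table,
    geosphere,
    mgcv,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'argo-check.R'
    'diveTherm-package.R'
    'gridded-field.R'
    'matchup.R'
    'pipeline.R'
    'synthetic-model.R'
    'synthetic-truth.R'
    'synthetic-turtles.R'
    'tag-decoder.R'
    'utils.R'
    'validation-stats.R'
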