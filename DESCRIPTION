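Package: sealplume
Title: Detecting Subglacial Discharge Plumes from Seal-Borne CTD Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for dive profiles collected by seals carrying
    GPS-equipped conductivity-temperature-depth satellite relay data loggers
    (GPS-CTD-SRDLs) in a glacial fjord. Quality-controls and geolocates dive
    profiles, classifies dives by glacier-terminus region, decomposes each
    water sample into ambient, subglacial-runoff and glacial-meltwater
    fractions from conservation of mass, heat and salt, scores the temporal
    density of dive clustering at the terminus with a Monte-Carlo DBSCAN
    parameter sweep over moving time windows, and couples the clustering
    series to a surface-runoff series by peak detection and pairing. Includes
    a synthetic-campaign generator (stratified fjord, entrainment plume,
    runoff-driven seal behaviour) so the whole pipeline is testable
    closed-loop without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    mgcv,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
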