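Package: migrapheno
Title: Trend Decomposition, Geolocator Annotation and Breeding-Phenology
    Estimation for Long-Distance Migration
Version: 1.0.0
Authors@R:
    person("Rowan", "Ellis", email = "rowan.ellis@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing long-term change in the timing of
    long-distance bird migration from three data streams: a panel of
    directly observed migratory departures (population trend,
    within-subject-centred decomposition into within- and
    between-individual slopes, ANOVA-based repeatability, per-individual
    posterior slope simulation, return-rate checks), light-level
    geolocator traces with salt-water conductivity (non-stop flight
    detection from dry runs, migration timing parameters, incubation
    detection from daytime shading bouts, threshold geolocation, mixed
    model year trends), and gridded snow-cover and NDVI series
    (asymmetric-Gaussian snowmelt date estimation, smoothing-spline
    green-up estimation, regional phenology trends). Every stage is
    paired with a synthetic-data generator with known ground truth so the
    full pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
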