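Package: neonet
Title: Origin-Destination Networks of Neonatal Hospitalization Displacements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses origin-destination networks of hospital
    admissions occurring in the neonatal period (days 0-27 of life) outside the
    mother's municipality of residence. Provides a synthetic generator for
    state-level administrative health records (hospitalizations, live births,
    infant deaths, NICU bed counts and a municipality registry organised into
    health regions and macroregions), record-selection and biennial
    origin-destination aggregation, flow-weighted distance statistics per
    origin and per health region, regional health and service-supply
    indicators (neonatal mortality rate, NICU beds per 1,000 live births,
    birth-outcome proportions), percent variation between biennia, directed
    displacement graphs with in-degree/inflow metrics and GEXF/GraphML export,
    and random-intercept linear mixed models for biennial trends and
    adjusted associations with the neonatal mortality rate, including a
    simulation harness for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    igraph,
    lme4,
    geosphere,
    xml2,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
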