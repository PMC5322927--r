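Package: fieldwork
Title: Field Workability, Drought Risk and Season Length Under Climate Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agro-climatological risk modelling pipeline: a stochastic daily
    weather generator (first-order Markov precipitation occurrence with gamma
    amounts and seasonal-sinusoid temperatures), delta-change climate scenario
    perturbation, a single-layer bucket model for 10 cm volumetric soil
    moisture, grid-search calibration of day-of-year-trending field
    workability thresholds (soil moisture as a fraction of the plastic limit,
    and mid-range temperature) against weekly field-working-day reports, and
    downstream statistics: Thornthwaite monthly potential evapotranspiration,
    cumulative water-balance deficits and May-August risk odds, growing degree
    days, and frost-date season metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
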