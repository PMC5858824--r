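Package: ltbca
Title: Lead-Time-Biased Case Ascertainment in Screened Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulation of lead-time-biased case ascertainment
    (LTBCA) in observational risk-factor studies nested within screened
    populations. Models the preclinical sojourn time as a lognormal (or
    overdiagnosis mixture) distribution, fits continuous age-specific
    incidence curves to registry-style rate points and back-shifts them to
    preclinical onset intensities, represents age- and stratum-specific
    screening behaviour as step functions, and evaluates the counterfactual
    unscreened and screening-adjusted cumulative incidence integrals per
    risk-factor stratum. The ratio of the adjusted cumulative incidences
    across strata is the bias relative risk, which can be applied as a
    correction factor to two-by-two tables from nested case-control studies.
    An individual-level Monte Carlo microsimulation of the identical
    generative model serves as an independent oracle, and a sensitivity-
    analysis grid sweeps sojourn modes, standard deviations, screening
    sensitivities and overdiagnosis settings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
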