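Package: combotrans
Title: Translating In Vitro Drug-Combination Responses into In Vivo and
    Clinical Dose Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for translating in vitro panRAF plus MEK
    inhibitor combination viability screens into in vivo and clinical dose
    predictions. Implements log-logistic dose-response fitting with
    matrix smoothing, HSA and Bliss synergy scoring, conversion of
    relative viability into the GR growth-rate-inhibition metric and
    control-normalized growth rates, free-drug projection of measured or
    simulated exposures onto dose-response surfaces, a one-compartment
    population pharmacokinetic simulator with lognormal interindividual
    variability, xenograft tumor-volume prediction under exponential
    growth, a coarse-grained MAPK signaling ODE model with ERK-mediated
    negative feedback on RAF, and the biexponential clinical
    tumor-growth-inhibition model with per-subject fitting. Includes
    synthetic-data generators emulating the statistical structure of
    combination screens, PK populations, xenograft volume series, and
    clinical tumor-size series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
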