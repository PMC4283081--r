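Package: gmscostsim
Title: Stratified Monte Carlo Projection of GMS Pharmaceutical Costs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Projects General Medical Services (GMS) prescribing costs for
    Ireland by region, gender and age cohort. Provides transcribed 2007
    claims-rate and average-cost-per-claim tables over the 160 strata of the
    eight former health boards, a seeded synthetic generator for PCRS-like
    claims databases, population projections and coverage histories, scenario
    construction from 95 percent confidence intervals, coverage projection
    with a capping adjustment for rates above one, and a stratified Monte
    Carlo cost simulator with a multiplicative Gaussian error ensemble,
    together with descriptive and main-effects reporting of the draw
    ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
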