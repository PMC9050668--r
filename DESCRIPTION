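Package: canlife
Title: Cohort Life Tables for Companion Dog Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds complete cohort life tables for companion-dog mortality from
    individual death records: keyword screening of free-text clinical and
    treatment fields for candidate deaths, cleaning and cohort inclusion rules
    with an explicit observation window, stratified life tables with a
    one-year age interval and an open final interval, eligibility-gated
    empirical bootstrap confidence intervals for life expectancy, and derived
    longevity metrics such as the age at which life expectancy drops below a
    threshold. A parametric registry simulator (constant, Gompertz-Makeham or
    piecewise hazards, with birth-cohort growth to emulate popularity bias)
    lets every stage run and validate without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
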