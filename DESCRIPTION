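Package: carpsim
Title: Markov Microsimulation of Coronary Revascularization Requirements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic multi-state (Markov) microsimulation of coronary heart
    disease (CHD) and coronary artery revascularization procedure (CARP) history
    for a population cohort. Annual event risks stratified by age, sex, calendar
    year and CHD/CARP history state drive year-by-year simulation of hospital
    admissions, bypass surgery (CABG), percutaneous intervention (PCI) and death,
    with replicate averaging. Linear trends fitted to recent risk estimates are
    extrapolated forward and modified under declarative scenarios (level-off,
    multiplicative scaling) to project procedure demand; a deterministic
    expectation engine mirrors the stochastic rule for exact testing, and a
    synthetic-data generator provides cohorts and risk-table histories with the
    qualitative structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
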