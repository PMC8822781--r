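Package: morbsim
Title: Comorbidity-Adjusted Life Expectancy by State-Transition Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and comorbidity-specific life expectancy from
    person-year register data by a discrete-time state-transition
    microsimulation. Annual transition models for death (logistic regression
    on a quadratic-constant spline basis of the Charlson Comorbidity Index,
    a Drug Comorbidity Index, and their age interactions), for CCI change
    (occurrence plus two stratified Poisson size models), and for DCI change
    (occurrence, direction, and Gamma size models) are fitted from long-format
    cohort tables. Fitted parameter sets drive per-individual annual updates
    of vital status, CCI, and DCI up to age 105; life expectancy is the area
    under the simulated survival curve. Includes a synthetic-cohort generator
    with known ground truth, an exact finite-state survival oracle, and a
    validation battery (observed versus simulated survival, mean comorbidity
    trajectories, calibration tables, and leave-one-region-out
    cross-validation), plus a command-line interface over delimited text
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
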