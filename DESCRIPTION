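Package: gcdcaspk
Title: Population Pharmacokinetics of GCDCA-S as an Endogenous Biomarker
    of OATP1B3 and OAT3 Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled population pharmacokinetic models for the endogenous
    bile-acid sulfate GCDCA-S (glycochenodeoxycholic acid 3-O-sulfate) and the
    transporter inhibitors rifampicin (OATP1B3) and probenecid (OAT3).
    Implements the indirect-response turnover model of biomarker plasma
    concentration and urinary excretion with competitive-inhibition clearance
    terms, clinical-trial simulation against published cross-over study
    designs, nonlinear mixed-effects estimation by Laplace-approximate
    marginal likelihood, visual predictive checks, and simulation-based power
    calculations for the design of transporter drug-drug interaction studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
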