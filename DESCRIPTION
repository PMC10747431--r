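Package: benchdose
Title: Benchmark Dose Modeling and Toxicological Risk Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood benchmark dose (BMD) modeling for summarized
    quantal and continuous dose-response data in the style of the EPA BMDS
    dichotomous and continuous model suites: multistage, gamma, Weibull,
    log-logistic, log-probit, logistic, probit, quantal-linear and
    dichotomous-Hill families for incidence data, and exponential, Hill,
    polynomial, power and linear families with a shared constant variance for
    group-summary data. Benchmark doses are defined by extra risk or relative
    deviation, lower confidence limits (BMDL) by profile likelihood, and fits
    are classified and ranked with the standard viability and recommendation
    rules. Downstream risk arithmetic derives acceptable daily intakes,
    maximum residue levels and margins of exposure from a point of departure
    and an uncertainty-factor ledger. Includes seeded simulation of
    dose-response datasets and the isoeugenol gavage-study endpoints as
    worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
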