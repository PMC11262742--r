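Package: claimscreen
Title: Statistical Fraud Screening for Daily Antigen-Test Billing Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens daily COVID-19 antigen-test billing claims from test
    centres for statistical signs of fraud. Implements four detectors
    (unusually high daily test volume within centre category, suspiciously
    low positivity via a Poisson regression with crossed random intercepts
    for centre and calendar week and a log-tests offset, deviation of
    leading digits from Benford's law, and deviation of last digits from
    uniformity), flag combination rules, and agreement/validity metrics
    against an external suspicion label (positive and negative overlap,
    incremental share, incremental predictive validity). Includes a
    synthetic claims generator with injectable fraud behaviours (volume
    inflation, positivity suppression, digit rounding, count fabrication)
    and imperfect suspicion/corroboration labels, so the full pipeline is
    testable without confidential billing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
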