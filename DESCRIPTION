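Package: dhurdle
Title: Double-Hurdle Models for Household Out-of-Pocket Pharmaceutical
    Expenditure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of Cragg-type double-hurdle
    models for non-negative household expenditure outcomes with exact
    zeros, as used to study out-of-pocket pharmaceutical spending in
    household budget surveys. The first hurdle is a probit participation
    equation; the second is a truncated-normal (linear) or lognormal
    (exponential) expenditure equation, with optionally correlated latent
    errors. Includes a Wald test of error independence, likelihood-ratio
    goodness of fit and McFadden pseudo R-squared, Table-style descriptive
    summaries with Rial-to-USD conversion, a synthetic household survey
    generator emulating an elderly-household expenditure survey, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse,
    withr
Config/testthat/edition: 3
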