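Package: hsmradjust
Title: Hospital Standardised Mortality Ratios Under Readmission Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how readmissions bias casemix-adjusted
    in-hospital mortality ratios. Links admission records into per-patient
    histories, numbers each patient's n-th admission, builds the mutually
    exclusive patient view P(m) and the overlapping admission view A(n),
    fits stratified casemix logistic risk models, computes standardised
    mortality ratios (SMR/HSMR) with Byar, exact Poisson or normal
    confidence limits, and implements admission frequency as an additional
    adjustment variable. A synthetic-cohort generator with a latent
    per-admission risk reduction for frequently admitted patients makes the
    whole pipeline testable without access to registry data, and a packaged
    worked example reproduces the per-class mortality analysis of a
    published five-year, six-hospital cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
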