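Package: cbrisk
Title: Risks and Relative Risks from Case-Base Studies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Regression-based estimation of odds ratios, absolute risks and
    relative risks from case-base studies, in which cases are sampled from
    incident diseased subjects and a base (control) sample is drawn from the
    whole study population regardless of disease status. A logistic model is
    fitted to the recruited subjects and its intercept is corrected with the
    estimated probability that a diseased recruit belongs to the base sample,
    yielding absolute and relative risk estimates with delta-method Wald
    confidence intervals. Includes closed-form comparison estimators (Sato,
    Miettinen, case duplication), a synthetic-population simulator, a
    Monte-Carlo study runner, a design-precision calculator and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
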