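Package: reproclines
Title: Reproductive-Mode Clines and Offspring Body Condition in a
    Bimodal Viviparous Salamander
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for clinal variation in reproductive modes of
    a live-bearing salamander sampled along a hybrid-zone transect. Provides
    rule-based developmental staging of newborns from gill and pigmentation
    character stages, hierarchical classification of clutch and population
    reproductive modes with success-rate accounting, Scaled Mass Index body
    condition via standardized-major-axis allometry, correspondence analysis
    of population-by-stage contingency tables, and a restricted
    maximum-likelihood linear mixed model of log body condition with nested
    random intercepts and reproductive-mode-specific residual variances,
    including estimated marginal means with Tukey contrasts, intraclass
    correlation, and marginal/conditional R-squared. A synthetic transect
    generator reproduces the statistical structure the analysis assumes so
    every step is testable without the field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    emmeans,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
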