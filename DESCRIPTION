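Package: audsev
Title: Dimensional Alcohol Use Disorder Severity Phenotyping from Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying alcohol use disorder (AUD) severity from
    ICD-10 coded statutory health insurance billing records.  Implements a
    five-level, deliberately overlapping severity phenotype (intoxication,
    harmful use, dependence, withdrawal, chronic end-organ damage), cohort
    and analysis-subsample construction from coverage and employment spells,
    Elixhauser comorbidity scoring, administrative prevalence estimation
    with Wilson confidence intervals, and a generalized estimating equation
    (GEE) Poisson regression of comorbidity on severity with exchangeable
    working correlation and robust standard errors.  A seeded synthetic
    claims generator with planted ground truth supports parameter-recovery
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
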