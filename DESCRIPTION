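Package: nova24r
Title: Self-Administered 24-Hour Dietary Recall Engine with Nova Food-Processing Classification and Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for building and validating automated, self-administered
    24-hour dietary recall instruments organised around the Nova food-processing
    classification. Provides a branching close-ended question engine over a
    structured food database; automatic disaggregation of culinary preparations
    into recipe ingredients; fractional imputation of missing type, source and
    preparation answers from population answer distributions; computation of the
    relative energy contribution of the four Nova groups; a multi-reviewer
    consensus workflow for assigning Nova groups; and the agreement-evaluation
    suite used to compare two dietary assessment tools, including two-way
    mixed-effects intraclass correlation coefficients with F-based confidence
    intervals, quintile cross-classification with prevalence-adjusted
    bias-adjusted kappa, paired mean comparisons and reliability-study
    sample-size calculation. A seeded synthetic-cohort generator makes every
    component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
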