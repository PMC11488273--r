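Package: edoutcomes
Title: Outcome Analysis for Adolescent Eating-Disorder Treatment in Higher Levels of Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing symptom change in adolescents treated for
    eating disorders at higher levels of care. Scores the EDE-Q, PHQ-9 and
    GAD-7 from item-level data; computes Jacobson-Truax reliable-change
    thresholds and clinical-significance cutoffs and classifies participants
    into the five-category change taxonomy; derives percent of expected body
    weight from sex/age LMS growth references; fits random-intercept linear
    mixed models by maximum likelihood and negative-binomial mixed models by
    the Laplace approximation, with semi-partial R-squared effect sizes and
    Bonferroni-controlled Wald tests; and generates fully seeded synthetic
    cohorts with realistic covariate-dependent missingness so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    glmmTMB,
    pracma,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
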