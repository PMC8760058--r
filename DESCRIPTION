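Package: chronomr
Title: Mendelian Randomisation and Circadian Misalignment Analysis of
    Diurnal Preference and Mental Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether diurnal preference (chronotype) is
    causally related to mental health and wellbeing. Implements weighted and
    standardised genetic risk scores with allele harmonisation and dosage QC;
    one-sample (two-stage least squares) and two-sample Mendelian
    randomisation estimators (inverse-variance weighted with multiplicative
    random effects, MR-Egger, weighted median and penalised weighted median)
    with heterogeneity diagnostics; the Composite Phase Deviation (CPD)
    actigraphy metric of behavioural circadian misalignment with its MSFsc
    sensitivity variant; observational logistic and proportional-odds models
    with the doubling-of-genetic-risk transform and Fisher's z sex-difference
    test; and a seeded synthetic-cohort generator that emulates the
    statistical structure of large biobank inputs so the full pipeline is
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
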