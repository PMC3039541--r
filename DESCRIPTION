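Package: relsurvgen
Title: Relative Survival as a Generalisability Measure for Ageing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the generalisability (external validity) of
    longitudinal cohort studies of older people by comparing cohort survival
    with that of the source population. Implements weighted actuarial cohort
    life tables with Ederer II expected survival from population life tables,
    interval-specific and cumulative relative survival with Greenwood-type
    confidence intervals, a multiplicative relative-mortality (SMR-type)
    proportional hazards regression on split person-time, chi-squared
    comparison of cohort and reference-survey category distributions,
    counterfactual direct standardisation of cumulative mortality, and a
    synthetic-data generator producing Gompertz population life tables and
    cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, yaml, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
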