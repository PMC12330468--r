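Package: phenomatch
Title: Comorbidity-Adjusted Case Definition and Propensity Matching for
    Under-Documented Phenotypes in Emergency-Department EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying likely-undiagnosed pediatric suicidality in
    emergency-department encounter data. Implements an ICD-10 phenotype case
    definition with severity subtypes (ideation, self-harm, attempt), a
    stratified conditional-probability comorbidity screen with chi-square
    testing and Bonferroni correction, DSM-5 category grouping, cumulative
    feature-matrix construction, logistic propensity-score estimation with
    greedy nearest-neighbour matching in logit space, covariate balance and
    score-distribution diagnostics, and enrichment statistics comparing matched
    comparators against ground truth. A seeded synthetic EHR generator with a
    latent, partially documented suicidality status stands in for protected
    hospital data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
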