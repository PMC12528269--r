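Package: ficompare
Title: Cumulative-Deficit Frailty Indices Across Survey and Routine Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cumulative-deficit frailty indices from two data
    modalities - coded electronic health record (EHR) extracts and
    survey-style deficit tables - and compares them at population level.
    Provides a synthetic cohort generator with known ground truth (age- and
    sex-dependent deficit prevalence, a shared latent factor inducing
    deficit correlation), ascertainment of deficits from coded events and
    of polypharmacy from prescription records, frailty-index scoring and
    categorisation, validated cross-source deficit harmonisation, and a
    comparison battery: direct age-sex standardised prevalence, per-deficit
    age-sex-adjusted odds ratios, two-sample Kolmogorov-Smirnov comparison
    of score distributions, and an interaction linear model for frailty
    scores. All user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
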