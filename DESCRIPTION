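Package: vancodose
Title: Vancomycin Initial-Dosing Nomogram and Trough-Monitoring Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decision-support tools for initial intravenous vancomycin dosing
    in critically ill adults. Implements a weight-by-renal-function dosing
    nomogram (MDRD4 estimated glomerular filtration rate, actual body weight,
    doses on a 250 mg grid capped at 4500 mg/day) together with its
    therapeutic-drug-monitoring plan and random-level redosing rules; a
    from-first-principles statistical battery (Pearson chi-square with optional
    continuity correction, Fisher's exact test, Mann-Whitney U, Kruskal-Wallis,
    and two-proportion sample-size calculation) for cohort evaluation;
    trough classification against the 10-20 mcg/ml therapeutic window with
    cohort summaries, between-group comparisons and weight/eGFR subgroup
    analyses; and a seeded synthetic-cohort generator with a one-compartment
    steady-state intermittent-infusion simulator for end-to-end testing
    without patient data.
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
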