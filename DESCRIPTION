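Package: saltshift
Title: Usual Sodium Intake Estimation and Food-Reformulation Scenario
    Modeling for Survey Dietary Recall Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates usual (long-run average) sodium intake in demographic
    subgroups from two-day 24-hour dietary recall data using a one-part
    Box-Cox amount model with person-level random effects, in the style of
    the National Cancer Institute method for nutrients consumed nearly every
    day.  Provides design-based (stratum/PSU/weight) descriptive statistics
    with Taylor-linearization standard errors, sodium-density metrics
    (mg/kcal, mg/g food) with cross-cycle trend tests, attribution of dietary
    sodium to the nine FNDDS food groups, and a food-reformulation scenario
    engine that scales sodium in targeted foods by a reduction factor and
    market-penetration factor and re-estimates usual intake.  A synthetic
    cohort generator emulating the structure of NHANES demographic and
    food-level recall files provides a parameter-recovery test surface for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
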