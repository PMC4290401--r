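# saltshift

Usual sodium intake estimation and food-reformulation scenario modeling
for survey dietary recall data.

## What it is for

Population sodium surveillance works from two 24-hour dietary recalls per
person (day 1 in person, day 2 by telephone) collected under a stratified
multi-stage sample design, as in NHANES. saltshift answers the questions
such analyses ask:

* **Usual intake.** How much sodium do demographic subgroups (age group ×
  gender × ethnicity) usually consume, and what fraction of each subgroup
  falls below the 1500 and 2300 mg/day guideline thresholds? A single
  recall day overstates the spread of intakes because day-to-day variation
  is large; saltshift fits a one-part (amount-only) measurement-error model
  in the style of the National Cancer Institute method:

  g(T_ij; λ) = x_ij′β + u_i + ε_ij,  u_i ~ N(0, σ²_b),  ε_ij ~ N(0, σ²_w),

  where g is the Box–Cox transform (λ chosen on a grid by profiled
  likelihood), x_ij holds subgroup cells plus weekend and interview-mode
  covariates, and usual intake is the expectation of the back-transform
  over day noise and the person effect's conditional distribution
  (Gauss–Hermite quadrature; lognormal closed form at λ = 0).

* **Trends.** Design-based regression of person-level sodium metrics —
  mg/day, mg/g food, mg/kcal — on the survey-cycle index, with
  stratum/PSU-clustered variance and a 0.01 significance level.

* **Sources.** Attribution of total dietary sodium to the nine FNDDS food
  groups per subgroup (weighted ratio of totals, normalised to 100%).

* **Reformulation scenarios.** Sodium in targeted foods is scaled by
  (per-food reduction factor) × (global scaling) × (market penetration);
  the usual-intake model is re-fitted on the modified recalls and subgroup
  reductions are reported as averages of individual reductions. A packaged
  scenario targets 953 foods across seven food groups at 20–30% maximum
  reduction (hollow salt-microsphere technology).

Standard errors for the nonlinear estimation chains come from a stratified
Rao–Wu PSU bootstrap; weighted means and trend slopes use Taylor
linearization. A synthetic cohort generator with known ground truth
(`generate_cohort()`) emulates the structure of the survey files so the
whole pipeline is testable without survey downloads.

## Worked example

```r
library(saltshift)

cfg     <- sim_config(n_persons = 2000, seed = 2026)   # study-condition defaults
cohort  <- generate_cohort(cfg)
demo    <- assign_age_groups(apply_population_filters(cohort$demographics))
#> Population filters: excluded 24 under age 2 and 9 pregnant/lactating; 1967 of 2000 retained
recalls <- subset(cohort$recalls, person_id %in% demo$person_id)

est <- estimate_usual_intake(recalls, demo, by = c("age_group", "gender"),
                             bootstrap = 100, seed = 1)
est$model
#> Usual-intake amount model: lambda = 0.00, sigma2_between = 0.0633, sigma2_within = 0.1232 (3934 day records)
est$subgroups[c("age_group", "gender", "mean", "se", "n",
                "prop_below_1500", "prop_below_2300")]
#>   age_group gender mean    se   n prop_below_1500 prop_below_2300
#> 1      2-18 female 2564  73.2 190        0.028889         0.39250
#> 2     19-50 female 3046  43.5 364        0.004753         0.16972
#> 3       51+ female 2668  72.5 432        0.016267         0.32395
#> 4      2-18   male 3238 123.7 187        0.001920         0.11254
#> 5     19-50   male 4422  73.6 376        0.000023         0.00797
#> 6       51+   male 3753  97.0 418        0.000473         0.04404
```

The fitted Box–Cox exponent is 0 (the generator is lognormal, so this is
the correct transform), and the variance components recover the configured
σ²_b = 0.0625 and σ²_w = 0.1225. Mean usual intakes (mg/day) carry
bootstrap standard errors; every subgroup sits well above 2300 mg/day on
average, and under 3% of any subgroup falls below 1500 mg/day.

Applying the packaged 953-food reformulation scenario at full market
penetration:

```r
rep <- run_scenario(recalls, demo, scenario(reformulation_scenario()),
                    by = "age_group")
rep$domains[c("age_group", "n", "reduction_mg", "current_mg", "post_mg",
              "pct_reduction")]
#>   age_group   n reduction_mg current_mg post_mg pct_reduction
#> 1      2-18 377        203.5       2907    2704         6.943
#> 2     19-50 740        261.9       3736    3474         6.957
#> 3       51+ 850        225.5       3210    2985         6.988
```

Each row reports the mean per-person usual-intake reduction (mg/day), the
usual intake before and after reformulation (the identity
`post = current − reduction` holds to numerical precision), and the percent
reduction averaged over individuals — here about 7% of intake, roughly
200–260 mg/day, consistent with published estimates of 185–323 mg/day
(6.3–8.4%) for this scenario at full penetration.

A command-line wrapper with subcommands `simulate`, `estimate`, `trend`,
`sources`, `scenario` and `sweep` is installed at
`system.file("cli", "saltshift", package = "saltshift")`.

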