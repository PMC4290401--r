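# Reformulation scenario engine: record-level algebra, conservation,
# end-to-end reports, penetration sweeps.

test_that("record-level reduction is the direct product of the three factors", {
  rec <- data.frame(person_id = 1, day = 1, food_code = "F1", grams = 100,
                    sodium_mg = 400, energy_kcal = 200, weekend = FALSE,
                    mode = "in_person")
  scn <- scenario(data.frame(food_code = "F1", max_reduction_fraction = 0.25))
  out <- apply_scenario(rec, scn)
  expect_equal(out$sodium_mg, 300)
  expect_equal(out$reduction_mg, 100)

  # zero penetration is the identity
  scn0 <- scenario(data.frame(food_code = "F1", max_reduction_fraction = 0.25),
                   penetration = 0)
  out0 <- apply_scenario(rec, scn0)
  expect_equal(out0$sodium_mg, rec$sodium_mg)
  expect_equal(out0$reduction_mg, 0)

  # untargeted foods unchanged; grams and kcal never change
  scnX <- scenario(data.frame(food_code = "OTHER", max_reduction_fraction = 1))
  outX <- apply_scenario(rec, scnX)
  expect_equal(outX$sodium_mg, rec$sodium_mg)
  expect_equal(out$grams, rec$grams)
  expect_equal(out$energy_kcal, rec$energy_kcal)
})

test_that("invalid scenario factors are rejected", {
  tab <- data.frame(food_code = "F1", max_reduction_fraction = 0.5)
  expect_error(scenario(tab, penetration = 1.5), "penetration")
  expect_error(scenario(tab, reduction_scaling = -0.1), "reduction_scaling")
  expect_error(
    scenario(data.frame(food_code = "F1", max_reduction_fraction = 2)),
    "\\[0,1\\]")
})

test_that("reduction is linear in penetration and conserves sodium", {
  fx <- make_cohort(n = 200, seed = 40)
  scn1 <- scenario(reformulation_scenario(), penetration = 1)
  scn05 <- scenario(reformulation_scenario(), penetration = 0.5)
  o1 <- apply_scenario(fx$recalls, scn1)
  o05 <- apply_scenario(fx$recalls, scn05)
  expect_equal(sum(o05$reduction_mg), sum(o1$reduction_mg) / 2,
               tolerance = 1e-12)
  # conservation per person-day
  key <- paste(o1$person_id, o1$day)
  orig <- tapply(o1$sodium_mg_original, key, sum)
  modi <- tapply(o1$sodium_mg, key, sum)
  redu <- tapply(o1$reduction_mg, key, sum)
  expect_lt(max(abs(modi - (orig - redu)) / orig), 1e-9)
})

test_that("total reduction is monotone in each of the three factors", {
  fx <- make_cohort(n = 150, seed = 41)
  base <- reformulation_scenario()
  red <- function(scaling, pen, rfac = 1) {
    tab <- base
    tab$max_reduction_fraction <- tab$max_reduction_fraction * rfac
    sum(apply_scenario(fx$recalls,
                       scenario(tab, scaling, pen))$reduction_mg)
  }
  expect_true(all(diff(sapply(c(0, 0.3, 0.7, 1), function(s) red(s, 1))) >= 0))
  expect_true(all(diff(sapply(c(0, 0.3, 0.7, 1), function(p) red(1, p))) >= 0))
  expect_true(all(diff(sapply(c(0.2, 0.6, 1), function(f) red(1, 1, f))) >= 0))
})

test_that("stochastic assignment converges to the expected-value reduction", {
  fx <- make_cohort(n = 80, seed = 50)
  tab <- reformulation_scenario()
  exp_red <- sum(apply_scenario(
    fx$recalls, scenario(tab, penetration = 0.4))$reduction_mg)
  scn_s <- scenario(tab, penetration = 0.4, mode = "stochastic_assignment")
  draws <- vapply(1:500, function(s) {
    sum(apply_scenario(fx$recalls, scn_s, seed = s)$reduction_mg)
  }, numeric(1))
  expect_lt(abs(mean(draws) - exp_red) / exp_red, 0.01)
})

test_that("noise-free scenario report matches the closed form exactly", {
  fx <- make_noise_free(n = 40, share = 0.28)
  scn <- scenario(reformulation_scenario())   # grain food at 25% reduction
  rep <- run_scenario(fx$recalls, fx$demo, scn, by = "age_group",
                      formula = ~1)
  d <- rep$domains
  expect_equal(d$pct_reduction, 7, tolerance = 1e-9)
  expect_equal(d$reduction_mg, 0.07 * d$current_mg, tolerance = 1e-9)
  expect_equal(d$post_mg, d$current_mg - d$reduction_mg, tolerance = 1e-9)
})

test_that("an empty scenario changes nothing", {
  fx <- make_cohort(n = 120, seed = 60)
  scn <- scenario(data.frame(food_code = character(0),
                             max_reduction_fraction = numeric(0)))
  rep <- run_scenario(fx$recalls, fx$demo, scn, by = "gender")
  expect_equal(rep$domains$reduction_mg, rep(0, nrow(rep$domains)),
               tolerance = 1e-9)
  expect_equal(rep$domains$post_mg, rep$domains$current_mg, tolerance = 1e-9)
})

test_that("report identity and bootstrap SEs hold on a generated cohort", {
  fx <- make_cohort(n = 400, seed = 61)
  scn <- scenario(reformulation_scenario())
  rep <- run_scenario(fx$recalls, fx$demo, scn, by = "gender",
                      bootstrap = 10, seed = 2)
  d <- rep$domains
  expect_equal(d$post_mg, d$current_mg - d$reduction_mg, tolerance = 1e-9)
  expect_true(all(d$reduction_mg >= 0))
  expect_true(all(d$pct_reduction >= 0 & d$pct_reduction <= 100))
  expect_true(all(is.finite(d$reduction_mg_se) & d$reduction_mg_se > 0))
})

test_that("per-group breakdown sums to roughly the total reduction", {
  fx <- make_cohort(n = 400, seed = 62)
  scn <- scenario(reformulation_scenario())
  rep <- run_scenario(fx$recalls, fx$demo, scn, by = "gender",
                      by_group = TRUE)
  g <- rep$groups
  expect_setequal(unique(g$group_id), c(1:5, 7, 8))
  shares <- tapply(g$share_of_total_reduction_pct, g$gender, sum)
  # sub-scenario reductions are estimated independently; shares should
  # reconstruct ~100% of the total
  expect_true(all(abs(shares - 100) < 10))
  expect_true(all(g$within_group_pct > 0 & g$within_group_pct < 100))
})

test_that("penetration sweep is linear on the noise-free fixture and sorted", {
  fx <- make_noise_free(n = 30, share = 0.28)
  scn <- scenario(reformulation_scenario())
  expect_warning(
    sw <- penetration_sweep(fx$recalls, fx$demo, scn, c(1, 0, 0.5),
                            by = "age_group", formula = ~1),
    "sort")
  expect_equal(sw$penetration, c(0, 0.5, 1))
  expect_equal(sw$reduction_mg[1], 0, tolerance = 1e-9)
  expect_equal(sw$reduction_mg[2], sw$reduction_mg[3] / 2, tolerance = 1e-9)
  # consistency with a single run at penetration 1
  one <- run_scenario(fx$recalls, fx$demo, scn, by = "age_group", formula = ~1)
  expect_equal(sw$reduction_mg[3], one$domains$reduction_mg, tolerance = 1e-12)
  expect_error(penetration_sweep(fx$recalls, fx$demo, scn, c(0.5, 2)),
               "\\[0, 1\\]")
})
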