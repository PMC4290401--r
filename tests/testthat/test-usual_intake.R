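# Amount model: Box-Cox transform, fitting, back-transformation, subgroup
# summaries.

test_that("Box-Cox transform matches hand-evaluated values", {
  for (lam in c(0, 0.3, 0.5, 1)) expect_equal(boxcox(1, lam), 0)
  expect_equal(boxcox(exp(1), 0), 1)
  expect_equal(boxcox(9, 0.5), 4)          # (sqrt(9) - 1) / 0.5
  expect_error(boxcox(-1, 0.5), "positive")
  expect_error(boxcox(0, 0), "positive")
  # strictly increasing, and inverse round-trips
  x <- c(0.5, 1, 2, 10, 100)
  for (lam in c(0, 0.25, 1)) {
    y <- boxcox(x, lam)
    expect_true(all(diff(y) > 0))
    expect_equal(boxcox_inv(y, lam), x, tolerance = 1e-12)
  }
})

test_that("noise-free data give zero within-person variance and exact predictions", {
  fx <- make_noise_free(n = 40)
  m <- fit_amount_model(fx$recalls, fx$demo, formula = ~1)
  expect_lt(m$sigma2_within, 1e-6)
  ui <- usual_intake_per_person(m, fx$recalls, fx$demo)
  ui <- ui[order(ui$person_id), ]
  expect_equal(ui$usual_mg, fx$totals, tolerance = 1e-9)
})

test_that("amount model recovers the generator's parameters", {
  fx <- make_cohort(n = 2000, seed = 303)
  m <- fit_amount_model(fx$recalls, fx$demo)
  expect_lte(abs(m$lambda - 0), 0.15)
  expect_lt(abs(m$sigma2_within - 0.35^2) / 0.35^2, 0.20)
  expect_lt(abs(m$sigma2_between - 0.25^2) / 0.25^2, 0.20)
  ui <- usual_intake_per_person(m, fx$recalls, fx$demo)
  tr <- merge(ui, fx$truth, by = "person_id")
  expect_lt(abs(mean(tr$usual_mg) / mean(tr$true_usual_intake_mg) - 1), 0.03)
})

test_that("estimates are invariant to weight rescaling and person duplication", {
  fx <- make_cohort(n = 250, seed = 55)
  m1 <- fit_amount_model(fx$recalls, fx$demo)

  demo_s <- fx$demo
  demo_s$weight <- demo_s$weight * 37.5
  m2 <- fit_amount_model(fx$recalls, demo_s)
  expect_equal(m1$lambda, m2$lambda)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-10)
  expect_equal(m1$sigma2_between, m2$sigma2_between, tolerance = 1e-10)
  expect_equal(m1$sigma2_within, m2$sigma2_within, tolerance = 1e-10)

  # duplicate every person with new ids and half the weight
  shift <- max(fx$demo$person_id)
  demo_d <- rbind(fx$demo, transform(fx$demo, person_id = person_id + shift))
  demo_d$weight <- demo_d$weight / 2
  rec_d <- rbind(fx$recalls, transform(fx$recalls, person_id = person_id + shift))
  m3 <- fit_amount_model(rec_d, demo_d)
  expect_equal(m1$lambda, m3$lambda)
  expect_equal(m1$beta, m3$beta, tolerance = 1e-8)
  expect_equal(m1$sigma2_between, m3$sigma2_between, tolerance = 1e-8)
  expect_equal(m1$sigma2_within, m3$sigma2_within, tolerance = 1e-8)
})

test_that("identifiability and domain errors are raised", {
  fx <- make_cohort(n = 30, seed = 6)
  rec1 <- fx$recalls[fx$recalls$day == 1, ]
  expect_error(fit_amount_model(rec1, fx$demo), "two recall days",
               class = "saltshift_identifiability_error")
  rec_bad <- fx$recalls
  rec_bad$sodium_mg <- 0
  expect_error(fit_amount_model(rec_bad, fx$demo), "non-positive",
               class = "saltshift_domain_error")
})

test_that("lognormal closed form matches quadrature at lambda = 0", {
  fx <- make_cohort(n = 300, seed = 14)
  m <- fit_amount_model(fx$recalls, fx$demo, lambda_grid = 0)
  ui <- usual_intake_per_person(m, fx$recalls, fx$demo)

  # closed form: exp(mu_i + (v_i + sigma2_w)/2) with the same conditional
  # person-effect moments the model uses
  pd <- saltshift:::person_day_totals(fx$recalls, fx$demo)
  X <- saltshift:::amount_design_matrix(m$formula, pd, pd$weekend, pd$telephone)
  e <- as.vector(log(pd$total_mg) - X[, m$colnames] %*% m$beta)
  ebar <- tapply(e, pd$person_id, mean)
  nd <- as.vector(table(pd$person_id)[names(ebar)])
  k <- m$sigma2_between / (m$sigma2_between + m$sigma2_within / nd)
  v <- (1 - k) * m$sigma2_between
  demo_ord <- fx$demo[match(names(ebar), as.character(fx$demo$person_id)), ]
  Xr <- saltshift:::amount_design_matrix(
    m$formula, demo_ord, rep(m$weekend_frac, nrow(demo_ord)),
    rep(m$telephone_frac, nrow(demo_ord)))
  closed <- exp(as.vector(Xr[, m$colnames] %*% m$beta) + k * as.vector(ebar) +
                  (v + m$sigma2_within) / 2)
  ord <- match(demo_ord$person_id, ui$person_id)
  expect_lt(max(abs(ui$usual_mg[ord] - closed) / closed), 1e-6)
})

test_that("quadrature is converged at the default node count", {
  fx <- make_cohort(n = 200, seed = 23)
  m9 <- fit_amount_model(fx$recalls, fx$demo, n_quadrature = 9)
  m41 <- m9
  m41$n_quadrature <- 41L
  u9 <- usual_intake_per_person(m9, fx$recalls, fx$demo)
  u41 <- usual_intake_per_person(m41, fx$recalls, fx$demo)
  expect_lt(max(abs(u9$usual_mg - u41$usual_mg) / u41$usual_mg), 1e-4)
  m2 <- m9
  m2$n_quadrature <- 2L
  expect_error(usual_intake_per_person(m2, fx$recalls, fx$demo), "3 nodes")
})

test_that("usual intake is strictly increasing in the conditional mean", {
  gh_mono <- function(lambda) {
    mu <- seq(-1, 30, length.out = 40)
    vals <- saltshift:::gh_expect(function(s) boxcox_inv(s, lambda), mu, 0.2, 21)
    all(diff(vals) > 0)
  }
  expect_true(gh_mono(0))
  expect_true(gh_mono(0.4))
  expect_true(gh_mono(1))
})

test_that("subgroup summary reduces to the arithmetic mean under equal weights", {
  fx <- make_noise_free(n = 30)
  m <- fit_amount_model(fx$recalls, fx$demo, formula = ~1)
  ui <- usual_intake_per_person(m, fx$recalls, fx$demo)
  s <- subgroup_summary(ui, fx$demo, by = "age_group", model = m)
  expect_equal(s$mean, mean(ui$usual_mg), tolerance = 1e-12)
  expect_equal(s$n, 30L)
})

test_that("planted subgroup ordering is recovered and thresholds nest", {
  slm <- default_subgroup_log_means()
  # plant a clean White > Black > Hispanic ordering in every cell
  slm$log_mean <- 8 + 0.25 * (slm$ethnicity == "Non-Hispanic White") +
    0.12 * (slm$ethnicity == "Non-Hispanic Black")
  fx <- make_cohort(n = 2000, seed = 444, subgroup_log_means = slm)
  est <- estimate_usual_intake(fx$recalls, fx$demo, by = "ethnicity",
                               bootstrap = 0)
  s <- est$subgroups
  m_of <- function(e) s$mean[s$ethnicity == e]
  expect_gt(m_of("Non-Hispanic White"), m_of("Non-Hispanic Black"))
  expect_gt(m_of("Non-Hispanic Black"), m_of("Mexican American"))
  expect_gt(m_of("Non-Hispanic Black"), m_of("Other Hispanic"))
  # threshold nesting, model-implied and empirical
  expect_true(all(s$prop_below_1500 <= s$prop_below_2300 + 1e-12))
  expect_true(all(s$prop_below_1500_empirical <=
                    s$prop_below_2300_empirical + 1e-12))
  expect_true(all(s$prop_below_1500 >= 0 & s$prop_below_2300 <= 1))
  # "Other" ethnicity is estimated but not reported
  expect_false("Other" %in% s$ethnicity)
})

test_that("bootstrap SEs are returned and flagged for thin domains", {
  fx <- make_cohort(n = 300, seed = 81)
  est <- estimate_usual_intake(fx$recalls, fx$demo, by = "gender",
                               bootstrap = 15, seed = 5)
  expect_true(all(is.finite(est$subgroups$se)))
  expect_true(all(est$subgroups$se > 0))
})
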