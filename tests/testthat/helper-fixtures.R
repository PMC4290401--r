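# Shared fixtures and independent oracles for the test suite.

# Small filtered, age-grouped cohort built from the generator.
make_cohort <- function(n = 400, seed = 1, ...) {
  cfg <- sim_config(n_persons = n, seed = seed, ...)
  co <- generate_cohort(cfg)
  demo <- assign_age_groups(suppressMessages(apply_population_filters(co$demographics)))
  recalls <- co$recalls[co$recalls$person_id %in% demo$person_id, , drop = FALSE]
  list(demo = demo, recalls = recalls, truth = co$truth, config = cfg,
       foodgroups = co$foodgroups)
}

# Deterministic noise-free two-food fixture: every person eats one targeted
# grain food carrying `share` of the day total and one untargeted beverage
# food with the rest; both days identical.
make_noise_free <- function(n = 50, share = 0.28, seed = 99) {
  totals <- with_seed_test(seed, exp(stats::rnorm(n, 8, 0.3)))
  demo <- data.frame(
    person_id = seq_len(n), age_years = 30, gender = "male",
    ethnicity = "Non-Hispanic White", pregnant_or_lactating = FALSE,
    stratum = sprintf("S%d", rep_len(1:5, n)), psu = sprintf("P%d", rep_len(1:2, n)),
    weight = 1, cycle = "c1", stringsAsFactors = FALSE)
  demo <- assign_age_groups(demo)
  one_day <- function(d) data.frame(
    person_id = seq_len(n), day = d,
    food_code = rep(c("G5_00001", "G9_00001"), each = n),
    grams = rep(totals, 2) / 1.4,
    sodium_mg = c(share * totals, (1 - share) * totals),
    energy_kcal = rep(totals, 2) / 1.7,
    weekend = FALSE, mode = if (d == 2) "telephone" else "in_person",
    stringsAsFactors = FALSE)
  list(demo = demo, recalls = rbind(one_day(1), one_day(2)), totals = totals)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Brute-force textbook Taylor-linearization SE for a weighted (Hajek) mean:
# explicit loops over strata and PSUs, no shared code with the package.
oracle_taylor_se <- function(y, w, stratum, psu) {
  mu <- sum(w * y) / sum(w)
  W <- sum(w)
  v <- 0
  for (s in unique(stratum)) {
    rows_s <- which(stratum == s)
    psus <- unique(psu[rows_s])
    nh <- length(psus)
    if (nh < 2) next
    totals <- numeric(nh)
    for (j in seq_along(psus)) {
      rows <- rows_s[psu[rows_s] == psus[j]]
      totals[j] <- sum(w[rows] * (y[rows] - mu) / W)
    }
    v <- v + nh / (nh - 1) * sum((totals - mean(totals))^2)
  }
  sqrt(v)
}

# Random small survey design for oracle comparisons.
random_design <- function(seed) {
  with_seed_test(seed, {
    n_strata <- sample(2:5, 1)
    rows <- list()
    for (s in seq_len(n_strata)) {
      n_psu <- sample(2:4, 1)
      for (p in seq_len(n_psu)) {
        m <- sample(2:6, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = sprintf("S%d", s), psu = sprintf("P%d", p),
          y = stats::rnorm(m, 10, 3), w = stats::runif(m, 0.5, 3))
      }
    }
    do.call(rbind, rows)
  })
}

total_sodium <- function(recalls) sum(recalls$sodium_mg)

withr_local_tempdir <- function() {
  d <- tempfile("saltshift-test-")
  dir.create(d)
  d
}
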