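# Synthetic NHANES-shaped cohort generator with known ground truth.
#
# The generator emits the three tables the analysis pipeline consumes
# (demographics, two-day food-level recalls, and a person-level truth table)
# under a log-scale amount model: person-day sodium is
#   exp(mu[subgroup] + cycle shift + u_i + b_weekend*W + b_seq*D2 + eps_ij)
# with u_i ~ N(0, sigma_between^2) and eps_ij ~ N(0, sigma_within^2), and
# each day total is partitioned across food records according to the
# configured FNDDS food-group composition.

#' The nine FNDDS top-level food groups
#'
#' @return data.frame with `group_id` (1..9) and `group_name`
#' @export
fndds_groups <- function() {
  data.frame(
    group_id = 1:9,
    group_name = c(
      "Milk & Milk Products",
      "Meat, Poultry, Fish & Mixtures",
      "Eggs",
      "Dry Beans, Peas, Other Legumes, Nuts & Seeds",
      "Grain Products",
      "Fruits",
      "Vegetables",
      "Fats, Oils & Salad Dressings",
      "Sugars, Sweets & Beverages"
    ),
    stringsAsFactors = FALSE
  )
}

age_group_levels <- function() c("2-18", "19-50", "51+")
gender_levels <- function() c("male", "female")
ethnicity_levels <- function() {
  c("Mexican American", "Other Hispanic", "Non-Hispanic White",
    "Non-Hispanic Black", "Other")
}
reported_ethnicities <- function() ethnicity_levels()[1:4]

#' Default subgroup mean log usual sodium intake (log mg/day)
#'
#' One row per (age group x gender x ethnicity) cell.  The defaults were
#' chosen once so that, under the default variance components and weekend
#' effect, the implied subgroup mean usual intakes sit at the levels and in
#' the ordering reported for the contemporary US population: adults 19-50 >
#' other ages, males > females, Non-Hispanic White highest of the four
#' reported ethnicities, with adult means roughly 2.5-4.6 g/day.
#'
#' @return data.frame with columns age_group, gender, ethnicity, log_mean
#' @export
default_subgroup_log_means <- function() {
  eth <- reported_ethnicities()
  # rows: age group within gender; columns: MexAm, OthHisp, NHWhite, NHBlack
  male <- rbind(
    `2-18`  = c(7.925, 7.909, 7.988, 7.925),
    `19-50` = c(8.243, 8.239, 8.314, 8.198),
    `51+`   = c(7.967, 7.991, 8.159, 8.070)
  )
  female <- rbind(
    `2-18`  = c(7.710, 7.702, 7.749, 7.730),
    `19-50` = c(7.852, 7.862, 7.925, 7.919),
    `51+`   = c(7.732, 7.723, 7.815, 7.790)
  )
  out <- expand.grid(
    age_group = age_group_levels(), gender = gender_levels(),
    ethnicity = eth, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  pick <- function(a, g, e) {
    m <- if (g == "male") male else female
    m[a, match(e, eth)]
  }
  out$log_mean <- mapply(pick, out$age_group, out$gender, out$ethnicity)
  out
}

#' Default expected share of daily sodium by FNDDS food group
#'
#' Mirrors the contemporary US source-attribution profile: Grain Products and
#' Meat/Poultry/Fish/Mixtures jointly about two thirds of sodium, Milk and
#' Vegetables the next largest contributors, the remaining five groups under
#' 15\% combined.
#'
#' @return numeric length-9 vector summing to 1, ordered by group_id
#' @export
default_group_composition <- function() {
  c(0.090, 0.270, 0.025, 0.015, 0.400, 0.010, 0.090, 0.020, 0.080)
}

# Food-pool sizes per group.  Sized so that the packaged 953-food
# reformulation scenario covers roughly 30% of the sodium in each targeted
# group, i.e. scenario foods carry ~29% of total dietary sodium.
default_foods_per_group <- function() {
  c(55L, 950L, 60L, 95L, 1600L, 120L, 110L, 115L, 400L)
}

default_cycles <- function() {
  data.frame(cycle = "2007-2010", log_shift = 0,
             sodium_per_gram = 1.4, sodium_per_kcal = 1.7,
             stringsAsFactors = FALSE)
}

#' Simulation configuration for the synthetic cohort generator
#'
#' @param n_persons number of sampled persons
#' @param n_strata number of design strata
#' @param psus_per_stratum PSUs per stratum (>= 2, needed for variance
#'   estimation)
#' @param weight_cv coefficient of variation of the lognormal sampling
#'   weights (0 gives equal weights)
#' @param subgroup_log_means data.frame (age_group, gender, ethnicity,
#'   log_mean) of mean log usual sodium (log mg/day) per subgroup cell
#' @param sigma_between SD of the person-level log intake random effect
#' @param sigma_within SD of the day-level log deviation
#' @param beta_weekend additive log-scale effect of a weekend recall day
#' @param beta_sequence additive log-scale effect of the day-2 (telephone)
#'   recall
#' @param p_weekend probability a recall day falls on a weekend (default 3/7)
#' @param p_under2 probability a sampled person is under 2 years of age
#' @param p_pregnant probability a female aged 15-49 is pregnant or lactating
#' @param ethnicity_probs named sampling probabilities over the five
#'   ethnicity labels
#' @param group_composition length-9 expected share of daily sodium per FNDDS
#'   group (sums to 1)
#' @param foods_per_group distinct food codes per group; scalar or length-9
#' @param eaten_per_group number of food records emitted per group per
#'   person-day; scalar or length-9 (capped at foods_per_group)
#' @param concentration Dirichlet concentration for the day-level partition
#'   of sodium across groups (larger = closer to group_composition)
#' @param sodium_per_kcal mean sodium density of the diet, mg per kcal
#' @param sodium_per_gram mean sodium density of the diet, mg per g food
#' @param ratio_cv record-level coefficient of variation of the two density
#'   ratios
#' @param cycles data.frame (cycle, log_shift, sodium_per_gram,
#'   sodium_per_kcal): ordered survey cycles with per-cycle shift in mean log
#'   intake and per-cycle sodium densities; NA densities fall back to the
#'   global values
#' @param seed integer seed; identical config + seed gives identical output
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_persons = 2000L,
                       n_strata = 15L,
                       psus_per_stratum = 2L,
                       weight_cv = 0.5,
                       subgroup_log_means = default_subgroup_log_means(),
                       sigma_between = 0.25,
                       sigma_within = 0.35,
                       beta_weekend = 0.05,
                       beta_sequence = -0.06,
                       p_weekend = 3 / 7,
                       p_under2 = 0.01,
                       p_pregnant = 0.02,
                       ethnicity_probs = c(
                         "Mexican American" = 0.17, "Other Hispanic" = 0.13,
                         "Non-Hispanic White" = 0.40, "Non-Hispanic Black" = 0.20,
                         "Other" = 0.10),
                       group_composition = default_group_composition(),
                       foods_per_group = default_foods_per_group(),
                       eaten_per_group = c(2L, 3L, 1L, 1L, 4L, 1L, 2L, 1L, 3L),
                       concentration = 50,
                       sodium_per_kcal = 1.7,
                       sodium_per_gram = 1.4,
                       ratio_cv = 0.10,
                       cycles = default_cycles(),
                       seed = 1L) {
  if (length(foods_per_group) == 1L) foods_per_group <- rep(foods_per_group, 9L)
  if (length(eaten_per_group) == 1L) eaten_per_group <- rep(eaten_per_group, 9L)
  cfg <- structure(class = "sim_config", list(
    n_persons = as.integer(n_persons), n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum), weight_cv = weight_cv,
    subgroup_log_means = subgroup_log_means,
    sigma_between = sigma_between, sigma_within = sigma_within,
    beta_weekend = beta_weekend, beta_sequence = beta_sequence,
    p_weekend = p_weekend, p_under2 = p_under2, p_pregnant = p_pregnant,
    ethnicity_probs = ethnicity_probs,
    group_composition = group_composition,
    foods_per_group = as.integer(foods_per_group),
    eaten_per_group = as.integer(eaten_per_group),
    concentration = concentration,
    sodium_per_kcal = sodium_per_kcal, sodium_per_gram = sodium_per_gram,
    ratio_cv = ratio_cv, cycles = cycles, seed = as.integer(seed)
  ))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_persons < 1L)
    fail("saltshift_config_error", "n_persons: must be >= 1")
  if (cfg$psus_per_stratum < 2L)
    fail("saltshift_config_error",
         "psus_per_stratum: must be >= 2 (variance estimation needs >= 2 PSUs per stratum)")
  if (!(cfg$sigma_between >= 0))
    fail("saltshift_config_error", "sigma_between: must be >= 0")
  if (!(cfg$sigma_within >= 0))
    fail("saltshift_config_error", "sigma_within: must be >= 0")
  if (cfg$weight_cv < 0)
    fail("saltshift_config_error", "weight_cv: must be >= 0")
  gc_ <- cfg$group_composition
  if (length(gc_) != 9L || any(gc_ < 0))
    fail("saltshift_config_error",
         "group_composition: must be 9 nonnegative shares")
  if (abs(sum(gc_) - 1) > 1e-9)
    fail("saltshift_config_error",
         "group_composition: shares must sum to 1 (got %.12f)", sum(gc_))
  if (any(cfg$foods_per_group < 1L))
    fail("saltshift_config_error", "foods_per_group: must be >= 1 per group")
  assert_columns(cfg$subgroup_log_means,
                 c("age_group", "gender", "ethnicity", "log_mean"),
                 "subgroup_log_means")
  assert_columns(cfg$cycles, c("cycle", "log_shift"), "cycles")
  cfg
}

food_code <- function(group_id, index) sprintf("G%d_%05d", group_id, index)

#' Food-code to FNDDS-group map implied by a simulation config
#'
#' Enumerates every food code the generator can emit (codes `G<g>_<i>` for
#' group g and index i up to `foods_per_group[g]`).
#'
#' @param config a [sim_config()]
#' @return data.frame (food_code, group_id, group_name)
#' @export
synthetic_foodgroup_map <- function(config) {
  groups <- fndds_groups()
  out <- do.call(rbind, lapply(1:9, function(g) {
    n <- config$foods_per_group[g]
    data.frame(food_code = food_code(g, seq_len(n)), group_id = g,
               stringsAsFactors = FALSE)
  }))
  out$group_name <- groups$group_name[out$group_id]
  out
}

#' Partition one day's sodium total across food records
#'
#' Draws group shares from a Dirichlet distribution centred on `composition`,
#' then splits each group's sodium across `eaten_per_group` food records with
#' codes drawn from the group's code pool.  Sodium is conserved exactly.
#'
#' @param total_mg positive day total sodium (mg)
#' @param composition length-9 nonnegative shares summing to 1
#' @param foods_per_group pool size per group (scalar or length 9)
#' @param eaten_per_group records emitted per group (scalar or length 9;
#'   capped at the pool size)
#' @param concentration Dirichlet concentration parameter
#' @return data.frame (food_code, group_id, sodium_mg); sum of sodium_mg
#'   equals `total_mg` to within floating-point rounding
#' @export
partition_day_sodium <- function(total_mg, composition,
                                 foods_per_group = default_foods_per_group(),
                                 eaten_per_group = c(2L, 3L, 1L, 1L, 4L, 1L, 2L, 1L, 3L),
                                 concentration = 50) {
  if (!is.numeric(total_mg) || length(total_mg) != 1L || total_mg <= 0)
    fail("saltshift_domain_error", "total_mg: must be a single positive number")
  if (length(composition) == 0L)
    fail("saltshift_config_error", "composition: must not be empty")
  if (length(composition) != 9L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9)
    fail("saltshift_config_error",
         "composition: must be 9 nonnegative shares summing to 1")
  if (length(foods_per_group) == 1L) foods_per_group <- rep(foods_per_group, 9L)
  if (length(eaten_per_group) == 1L) eaten_per_group <- rep(eaten_per_group, 9L)
  eaten <- pmin(pmax(eaten_per_group, 1L), foods_per_group)

  shares <- rdirichlet1(concentration * composition)
  recs <- lapply(which(shares > 0), function(g) {
    k <- eaten[g]
    w <- rdirichlet1(rep(2, k))
    idx <- sample.int(foods_per_group[g], k, replace = TRUE)
    data.frame(food_code = food_code(g, idx), group_id = g,
               sodium_mg = total_mg * shares[g] * w,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Generate a synthetic survey cohort with ground truth
#'
#' Emits NHANES-shaped demographics, a two-day food-level recall table
#' (day 1 in-person, day 2 telephone), and a truth table holding each
#' person's long-run mean daily sodium intake
#' `exp(mu + u_i + sigma_within^2/2) * ((1-p) + p*exp(beta_weekend))`,
#' i.e. the real-life expectation over day noise and weekend occurrence
#' (the interview-sequence effect is a survey artifact and is excluded
#' from the truth).
#'
#' @param config a [sim_config()]
#' @return list of class `synthetic_cohort` with elements `demographics`,
#'   `recalls`, `truth`, `foodgroups` (the implied food-group map) and
#'   `config`
#' @export
generate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_persons
  cycles <- cfg$cycles
  n_cyc <- nrow(cycles)

  # --- demographics -------------------------------------------------------
  person_id <- seq_len(n)
  cyc_idx <- ((person_id - 1L) %% n_cyc) + 1L
  idx_in_cycle <- (person_id - 1L) %/% n_cyc   # 0-based rank within cycle
  stratum_i <- (idx_in_cycle %% cfg$n_strata) + 1L
  psu_i <- ((idx_in_cycle %/% cfg$n_strata) %% cfg$psus_per_stratum) + 1L
  stratum <- if (n_cyc > 1L) {
    sprintf("%s.S%02d", cycles$cycle[cyc_idx], stratum_i)
  } else sprintf("S%02d", stratum_i)
  psu <- sprintf("P%d", psu_i)

  gender <- sample(gender_levels(), n, replace = TRUE)
  ethnicity <- sample(names(cfg$ethnicity_probs), n, replace = TRUE,
                      prob = cfg$ethnicity_probs)
  under2 <- stats::runif(n) < cfg$p_under2
  age_years <- ifelse(under2, sample(0:1, n, replace = TRUE),
                      sample(2:85, n, replace = TRUE))
  preg <- gender == "female" & age_years >= 15 & age_years <= 49 &
    stats::runif(n) < cfg$p_pregnant
  weight <- if (cfg$weight_cv > 0) {
    sdl <- sqrt(log(1 + cfg$weight_cv^2))
    stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, n)

  demo <- data.frame(
    person_id = person_id, age_years = age_years, gender = gender,
    ethnicity = ethnicity, pregnant_or_lactating = preg,
    stratum = stratum, psu = psu, weight = weight,
    cycle = cycles$cycle[cyc_idx], stringsAsFactors = FALSE
  )

  # --- person-day log-scale model ----------------------------------------
  ag <- cut(pmax(age_years, 2), breaks = c(2, 18, 50, Inf),
            labels = age_group_levels(), include.lowest = TRUE)
  slm <- cfg$subgroup_log_means
  key <- paste(slm$age_group, slm$gender, slm$ethnicity, sep = "|")
  mu_cell <- slm$log_mean[match(paste(ag, gender, ethnicity, sep = "|"), key)]
  # "Other" ethnicity (not in the log-mean table): cell mean over the four
  # reported ethnicities of the same age group x gender
  if (anyNA(mu_cell)) {
    agg <- stats::aggregate(log_mean ~ age_group + gender, data = slm, FUN = mean)
    k2 <- paste(agg$age_group, agg$gender, sep = "|")
    nas <- which(is.na(mu_cell))
    mu_cell[nas] <- agg$log_mean[match(paste(ag, gender, sep = "|")[nas], k2)]
  }
  mu_cell <- mu_cell + cycles$log_shift[cyc_idx]

  u <- stats::rnorm(n, 0, cfg$sigma_between)

  nd <- 2L * n
  day <- rep(1:2, each = n)
  pd_person <- rep(person_id, 2L)
  weekend <- stats::runif(nd) < cfg$p_weekend
  eps <- if (cfg$sigma_within > 0) stats::rnorm(nd, 0, cfg$sigma_within) else numeric(nd)
  log_total <- rep(mu_cell, 2L) + rep(u, 2L) +
    cfg$beta_weekend * weekend + cfg$beta_sequence * (day == 2L) + eps
  total_mg <- exp(log_total)

  # --- food-level partition (vectorised over person-days) ----------------
  eaten <- pmin(pmax(cfg$eaten_per_group, 1L), cfg$foods_per_group)
  alpha <- cfg$concentration * cfg$group_composition
  act <- which(alpha > 0)
  G <- matrix(0, nd, 9L)
  for (g in act) G[, g] <- stats::rgamma(nd, shape = alpha[g], rate = 1)
  G <- G / rowSums(G)

  rec_list <- vector("list", length(act))
  spg <- cycles$sodium_per_gram[cyc_idx]
  spg[is.na(spg)] <- cfg$sodium_per_gram
  spk <- cycles$sodium_per_kcal[cyc_idx]
  spk[is.na(spk)] <- cfg$sodium_per_kcal
  sdl <- sqrt(log(1 + cfg$ratio_cv^2))
  for (j in seq_along(act)) {
    g <- act[j]
    k <- eaten[g]
    W <- matrix(stats::rgamma(nd * k, shape = 2, rate = 1), nd, k)
    W <- W / rowSums(W)
    sod <- as.vector(W * (total_mg * G[, g]))     # column-major: k blocks of nd
    idx <- sample.int(cfg$foods_per_group[g], nd * k, replace = TRUE)
    # densities vary by record; medians offset so person-level ratios of
    # totals are centred on the configured cycle density
    rate_g <- rep(spg, k) * exp(sdl^2 / 2 + stats::rnorm(nd * k, 0, sdl))
    rate_k <- rep(spk, k) * exp(sdl^2 / 2 + stats::rnorm(nd * k, 0, sdl))
    rec_list[[j]] <- data.frame(
      person_id = rep(pd_person, k), day = rep(day, k),
      food_code = food_code(g, idx),
      grams = sod / rate_g, sodium_mg = sod, energy_kcal = sod / rate_k,
      weekend = rep(weekend, k),
      mode = rep(ifelse(day == 2L, "telephone", "in_person"), k),
      stringsAsFactors = FALSE
    )
  }
  recalls <- do.call(rbind, rec_list)
  recalls <- recalls[order(recalls$person_id, recalls$day, recalls$food_code), ]
  rownames(recalls) <- NULL

  truth <- data.frame(
    person_id = person_id,
    true_usual_intake_mg = exp(mu_cell + u + cfg$sigma_within^2 / 2) *
      ((1 - cfg$p_weekend) + cfg$p_weekend * exp(cfg$beta_weekend)),
    person_random_effect = u
  )

  structure(class = "synthetic_cohort", list(
    demographics = demo, recalls = recalls, truth = truth,
    foodgroups = synthetic_foodgroup_map(cfg), config = cfg
  ))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d persons, %d recall records, %d strata x %d PSUs, %d cycle(s)\n",
    nrow(x$demographics), nrow(x$recalls), x$config$n_strata,
    x$config$psus_per_stratum, nrow(x$config$cycles)))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes demographics.csv, recalls.csv, foodgroups.csv and truth.csv in the
#' package's flat-file dialect (comma-separated, UTF-8, header row).
#'
#' @param cohort a [generate_cohort()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of paths written
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    demographics = file.path(dir, "demographics.csv"),
    recalls = file.path(dir, "recalls.csv"),
    foodgroups = file.path(dir, "foodgroups.csv"),
    truth = file.path(dir, "truth.csv")
  )
  utils::write.csv(cohort$demographics, paths["demographics"], row.names = FALSE)
  utils::write.csv(cohort$recalls, paths["recalls"], row.names = FALSE)
  utils::write.csv(cohort$foodgroups[c("food_code", "group_id")],
                   paths["foodgroups"], row.names = FALSE)
  utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
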