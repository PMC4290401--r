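# Flat-file IO, schema validation, and population filters.
#
# Dialect: comma-separated, UTF-8, header row with the canonical field
# names, "." decimal separator.  Four files: demographics.csv, recalls.csv,
# foodgroups.csv, scenario.csv.

demo_columns <- function() {
  c("person_id", "age_years", "gender", "ethnicity", "pregnant_or_lactating",
    "stratum", "psu", "weight", "cycle")
}
recall_columns <- function() {
  c("person_id", "day", "food_code", "grams", "sodium_mg", "energy_kcal",
    "weekend", "mode")
}

read_csv_checked <- function(path, what) {
  if (!file.exists(path))
    fail("saltshift_io_error", "%s: file not found: %s", what, path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a demographics table
#'
#' @param path CSV file in the package dialect
#' @return validated data.frame (see [validate_demographics()])
#' @export
read_demographics <- function(path) {
  validate_demographics(read_csv_checked(path, "demographics"))
}

#' Validate a demographics table
#'
#' Checks the schema (person id, age, gender, ethnicity, pregnancy/lactation
#' flag, stratum, PSU, sampling weight, cycle), uniqueness of person ids, and
#' strict positivity of weights.
#'
#' @param demo data.frame
#' @return the validated data.frame, with logical pregnancy flag
#' @export
validate_demographics <- function(demo) {
  assert_columns(demo, demo_columns(), "demographics")
  if (anyDuplicated(demo$person_id))
    fail("saltshift_schema_error", "demographics: person_id values not unique")
  if (!is.numeric(demo$weight)) {
    bad <- which(is.na(suppressWarnings(as.numeric(demo$weight))))[1]
    fail("saltshift_parse_error",
         "demographics: non-numeric weight at row %d", bad)
  }
  bad <- which(!is.finite(demo$weight) | demo$weight <= 0)
  if (length(bad))
    fail("saltshift_schema_error",
         "demographics: non-positive weight at row %d (person %s)",
         bad[1], demo$person_id[bad[1]])
  if (!is.numeric(demo$age_years) || any(demo$age_years < 0, na.rm = TRUE))
    fail("saltshift_schema_error", "demographics: age_years must be >= 0")
  demo$pregnant_or_lactating <- as.logical(demo$pregnant_or_lactating)
  demo
}

#' Read and validate a food-level recall table
#'
#' @param path CSV file in the package dialect
#' @return validated data.frame with logical `weekend`
#' @export
read_recalls <- function(path) {
  validate_recalls(read_csv_checked(path, "recalls"))
}

#' Validate a recall table
#'
#' @param recalls data.frame of food-level recall records
#' @return the validated data.frame
#' @export
validate_recalls <- function(recalls) {
  assert_columns(recalls, recall_columns(), "recalls")
  if (!all(recalls$day %in% c(1L, 2L)))
    fail("saltshift_schema_error", "recalls: day must be 1 or 2")
  bad <- which(!is.finite(recalls$grams) | recalls$grams <= 0)
  if (length(bad))
    fail("saltshift_schema_error", "recalls: non-positive grams at row %d", bad[1])
  bad <- which(!is.finite(recalls$sodium_mg) | recalls$sodium_mg < 0)
  if (length(bad))
    fail("saltshift_schema_error", "recalls: negative sodium_mg at row %d", bad[1])
  recalls$weekend <- as.logical(recalls$weekend)
  recalls
}

#' Read and validate a food-code to FNDDS-group map
#'
#' @param path CSV with columns food_code, group_id
#' @return validated data.frame with group_name attached
#' @export
read_foodgroups <- function(path) {
  validate_foodgroups(read_csv_checked(path, "foodgroups"))
}

#' Validate a food-group map
#'
#' @param map data.frame with food_code and group_id in 1..9
#' @return the validated map with `group_name` attached
#' @export
validate_foodgroups <- function(map) {
  assert_columns(map, c("food_code", "group_id"), "foodgroups")
  if (anyDuplicated(map$food_code))
    fail("saltshift_schema_error",
         "foodgroups: food_code mapped to more than one group")
  if (!all(map$group_id %in% 1:9))
    fail("saltshift_schema_error", "foodgroups: group_id must be in 1..9")
  map$group_name <- fndds_groups()$group_name[map$group_id]
  map
}

#' Read and validate a reformulation scenario table
#'
#' @param path CSV with columns food_code, max_reduction_fraction
#' @return validated data.frame
#' @export
read_scenario_table <- function(path) {
  validate_scenario_table(read_csv_checked(path, "scenario"))
}

#' Validate a scenario table
#'
#' @param tab data.frame with food_code and max_reduction_fraction in [0, 1]
#' @return the validated data.frame
#' @export
validate_scenario_table <- function(tab) {
  assert_columns(tab, c("food_code", "max_reduction_fraction"), "scenario")
  bad <- which(!is.finite(tab$max_reduction_fraction) |
                 tab$max_reduction_fraction < 0 | tab$max_reduction_fraction > 1)
  if (length(bad))
    fail("saltshift_schema_error",
         "scenario: max_reduction_fraction outside [0,1] at row %d", bad[1])
  if (anyDuplicated(tab$food_code))
    fail("saltshift_schema_error", "scenario: duplicate food_code")
  tab
}

#' Read the four pipeline input tables
#'
#' @param demo,recalls,foodgroups,scenario file paths; `foodgroups` and
#'   `scenario` may be NULL when a stage does not need them
#' @return named list of validated tables
#' @export
read_tables <- function(demo, recalls, foodgroups = NULL, scenario = NULL) {
  out <- list(
    demographics = read_demographics(demo),
    recalls = read_recalls(recalls)
  )
  if (!is.null(foodgroups)) out$foodgroups <- read_foodgroups(foodgroups)
  if (!is.null(scenario)) out$scenario <- read_scenario_table(scenario)
  out
}

#' Apply the surveillance population filters
#'
#' Removes children under age 2 and pregnant and/or lactating females.
#' Exclusion counts are attached as attribute `exclusions` and reported via
#' `message()`.
#'
#' @param demo validated demographics table
#' @return filtered table (possibly empty, with a warning)
#' @export
apply_population_filters <- function(demo) {
  assert_columns(demo, c("age_years", "pregnant_or_lactating"), "demographics")
  drop_age <- demo$age_years < 2
  drop_preg <- demo$pregnant_or_lactating & !drop_age
  keep <- !(drop_age | drop_preg)
  out <- demo[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(under_2 = sum(drop_age),
                               pregnant_or_lactating = sum(drop_preg))
  message(sprintf(
    "Population filters: excluded %d under age 2 and %d pregnant/lactating; %d of %d retained",
    sum(drop_age), sum(drop_preg), nrow(out), nrow(demo)))
  if (nrow(out) == 0L) warning("apply_population_filters: no persons retained")
  out
}

#' Assign surveillance age groups
#'
#' Adds an `age_group` factor with levels 2-18, 19-50 and 51+ (ages 18 and
#' 50 fall in the lower group, 19 and 51 open the next).
#'
#' @param demo demographics table with all ages >= 2 (filter first)
#' @return the table with an `age_group` column
#' @export
assign_age_groups <- function(demo) {
  assert_columns(demo, "age_years", "demographics")
  if (nrow(demo) && any(demo$age_years < 2))
    fail("saltshift_domain_error",
         "assign_age_groups: ages under 2 present; apply_population_filters first")
  demo$age_group <- cut(demo$age_years, breaks = c(2, 18, 50, Inf),
                        labels = age_group_levels(), include.lowest = TRUE)
  demo
}

#' The packaged 953-food salt-microsphere reformulation scenario
#'
#' The hollow-salt-microsphere reformulation programme targets 953 foods in
#' seven of the nine FNDDS groups: 17 Milk & Milk Products foods at 20\%
#' maximum sodium reduction, 304 Meat, Poultry, Fish & Mixtures foods at
#' 20-25\%, 20 Eggs foods at 25\%, 30 legume/nut/seed foods at 25\%, 511
#' Grain Products foods at 25\%, 35 Vegetables foods at 20-30\%, and 36
#' Fats, Oils & Salad Dressings foods at 25\%.  Ranged categories are
#' expanded as an evenly spaced sequence over the category's foods.  Food
#' codes are the first codes of each group's synthetic pool, so the scenario
#' applies directly to cohorts from [generate_cohort()].
#'
#' @return data.frame (food_code, group_id, max_reduction_fraction) with
#'   exactly 953 rows
#' @export
reformulation_scenario <- function() {
  batches <- list(
    list(group = 1L, n = 17L,  r = 0.20),
    list(group = 2L, n = 304L, r = c(0.20, 0.25)),
    list(group = 3L, n = 20L,  r = 0.25),
    list(group = 4L, n = 30L,  r = 0.25),
    list(group = 5L, n = 511L, r = 0.25),
    list(group = 7L, n = 35L,  r = c(0.20, 0.30)),
    list(group = 8L, n = 36L,  r = 0.25)
  )
  out <- do.call(rbind, lapply(batches, function(b) {
    r <- if (length(b$r) == 2L) seq(b$r[1], b$r[2], length.out = b$n) else rep(b$r, b$n)
    data.frame(food_code = food_code(b$group, seq_len(b$n)),
               group_id = b$group, max_reduction_fraction = r,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Published reference subgroup estimates for the packaged scenario
#'
#' National reference estimates (two-day recall surveillance, 2007-2010) of
#' usual sodium intake and its potential reduction under the packaged
#' 953-food reformulation scenario at full market penetration, by ethnicity
#' and adult age group: mean potential reduction (mg/day), current usual
#' intake (mg/day), usual intake after reduction (mg/day) and percent
#' reduction, each with standard errors.  Shipped for arithmetic
#' cross-checks of the scenario-report layout; the package does not attempt
#' to reproduce these population point estimates from synthetic data.
#'
#' @return data.frame, one row per ethnicity x age group
#' @export
reference_scenario_report <- function() {
  path <- system.file("extdata", "reference_scenario_report.csv",
                      package = "saltshift", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
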