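# Design-based descriptive statistics: weighted means with
# Taylor-linearization SEs, sodium-density metrics, and cross-cycle trend
# regression with stratum/PSU-clustered variance.

check_design <- function(stratum, psu, lonely = c("error", "collapse")) {
  lonely <- match.arg(lonely)
  tab <- table(tapply(psu, stratum, function(p) length(unique(p))))
  counts <- tapply(psu, stratum, function(p) length(unique(p)))
  lone <- names(counts)[counts < 2]
  if (length(lone)) {
    if (lonely == "error")
      fail("saltshift_design_error",
           "single-PSU stratum (lonely PSU): %s", paste(lone, collapse = ", "))
    # collapse: merge each lonely stratum with the next stratum in sort order
    strata <- sort(unique(stratum))
    repl <- stats::setNames(strata, strata)
    for (s in lone) {
      i <- match(s, strata)
      partner <- if (i < length(strata)) strata[i + 1L] else strata[i - 1L]
      repl[s] <- repl[partner]
    }
    stratum <- unname(repl[stratum])
  }
  stratum
}

#' Survey-weighted mean with Taylor-linearization standard error
#'
#' Point estimate is the Hajek ratio mean `sum(w*y)/sum(w)`.  The SE uses
#' the standard with-replacement first-stage approximation: linearized
#' scores are aggregated to stratum/PSU totals, and the variance is the sum
#' over strata of `n_h/(n_h-1)` times the squared deviations of PSU totals
#' from their stratum mean.
#'
#' @param values numeric outcome vector
#' @param weights positive sampling weights
#' @param stratum,psu design labels, parallel to `values`
#' @param lonely handling of single-PSU strata: "error" (default) or
#'   "collapse" (merge with the adjacent stratum in sort order)
#' @return list with `mean`, `se`, `n`, and design degrees of freedom `df`
#'   (PSUs minus strata)
#' @export
weighted_mean_se <- function(values, weights, stratum, psu,
                             lonely = c("error", "collapse")) {
  stopifnot(length(values) == length(weights),
            length(values) == length(stratum), length(values) == length(psu))
  if (any(!is.finite(weights) | weights <= 0))
    fail("saltshift_domain_error", "weights must be positive")
  mean_hat <- sum(weights * values) / sum(weights)

  stratum <- check_design(stratum, psu, lonely)
  z <- weights * (values - mean_hat) / sum(weights)
  cl <- paste(stratum, psu, sep = "\r")
  t_hk <- tapply(z, cl, sum)
  st_of_cl <- sub("\r.*$", "", names(t_hk))
  var_hat <- 0
  df <- 0L
  for (s in unique(st_of_cl)) {
    th <- t_hk[st_of_cl == s]
    nh <- length(th)
    df <- df + nh - 1L
    if (nh > 1L) var_hat <- var_hat + nh / (nh - 1) * sum((th - mean(th))^2)
  }
  list(mean = mean_hat, se = sqrt(var_hat), n = length(values), df = df)
}

#' Person-level sodium density metrics
#'
#' Collapses food-level recall records to person-level 2-day means: daily
#' sodium (mg/day), sodium per unit energy (mg/kcal) and sodium per unit
#' food mass (mg/g), each computed as the ratio of the person's mean daily
#' sodium to mean daily energy (resp. food mass).  Persons with zero energy
#' or gram totals are excluded with a warning.
#'
#' @param recalls validated recall table
#' @return data.frame (person_id, n_days, sodium_mg_day, energy_kcal_day,
#'   grams_day, sodium_per_kcal, sodium_per_gram)
#' @export
density_metrics <- function(recalls) {
  assert_columns(recalls, c("person_id", "day", "sodium_mg", "energy_kcal",
                            "grams"), "recalls")
  key <- paste(recalls$person_id, recalls$day, sep = "\r")
  sod <- tapply(recalls$sodium_mg, key, sum)
  kcal <- tapply(recalls$energy_kcal, key, sum)
  grm <- tapply(recalls$grams, key, sum)
  pid <- sub("\r.*$", "", names(sod))

  agg <- function(x) as.vector(tapply(x, pid, mean))
  ids <- sort(unique(pid))
  out <- data.frame(
    person_id = ids,
    n_days = as.vector(tapply(pid, pid, length)),
    sodium_mg_day = agg(sod),
    energy_kcal_day = agg(kcal),
    grams_day = agg(grm),
    stringsAsFactors = FALSE
  )
  # restore numeric person ids when they round-trip cleanly
  suppressWarnings({
    num <- as.numeric(out$person_id)
    if (!anyNA(num)) {
      out$person_id <- num
      out <- out[order(out$person_id), ]
      rownames(out) <- NULL
    }
  })
  bad <- out$energy_kcal_day <= 0 | out$grams_day <= 0
  if (any(bad)) {
    warning(sprintf(
      "density_metrics: excluded %d person(s) with zero energy or gram totals",
      sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out$sodium_per_kcal <- out$sodium_mg_day / out$energy_kcal_day
  out$sodium_per_gram <- out$sodium_mg_day / out$grams_day
  out
}

# Design-based weighted least squares with stratum/PSU-clustered
# (linearized) covariance.  Returns beta, se, df.
svy_lm <- function(X, y, w, stratum, psu, lonely = "error") {
  stratum <- check_design(stratum, psu, lonely)
  A <- crossprod(X, w * X)
  beta <- solve(A, crossprod(X, w * y))
  e <- as.vector(y - X %*% beta)
  U <- X * (w * e)                      # score contributions per row
  cl <- paste(stratum, psu, sep = "\r")
  Ucl <- rowsum(U, cl)
  st_of_cl <- sub("\r.*$", "", rownames(Ucl))
  meat <- matrix(0, ncol(X), ncol(X))
  df <- 0L
  for (s in unique(st_of_cl)) {
    Uh <- Ucl[st_of_cl == s, , drop = FALSE]
    nh <- nrow(Uh)
    df <- df + nh - 1L
    if (nh > 1L) {
      Uc <- sweep(Uh, 2, colMeans(Uh))
      meat <- meat + nh / (nh - 1) * crossprod(Uc)
    }
  }
  Ainv <- solve(A)
  V <- Ainv %*% meat %*% Ainv
  list(beta = as.vector(beta), se = sqrt(pmax(diag(V), 0)),
       df = df - (ncol(X) - 1L), names = colnames(X))
}

#' Cross-cycle trend regression of sodium metrics
#'
#' For each reporting domain and metric, fits a survey-weighted linear
#' regression of the person-level metric on the cycle index (0, 1, 2, ...)
#' with design-based (stratum/PSU-clustered) variance, and flags
#' significance of the slope at `alpha`.  Weights are divided by the number
#' of cycles combined, the standard convention when pooling survey cycles
#' (it does not affect point estimates).
#'
#' @param density person-level metrics from [density_metrics()]
#' @param demo demographics with design columns, `cycle`, and the domain
#'   columns in `by` (run [assign_age_groups()] first if grouping by age)
#' @param metrics subset of c("sodium_mg_day", "sodium_per_gram",
#'   "sodium_per_kcal")
#' @param by domain columns of `demo`; NULL for a single overall domain
#' @param cycle_levels ordered cycle labels; default sorted unique cycles
#' @param alpha significance level (default 0.01)
#' @param level "person" (default) regresses person-level records;
#'   "cycle_mean" regresses the per-cycle weighted means on the index
#' @param lonely lonely-PSU handling, see [weighted_mean_se()]
#' @return data.frame: domain columns, metric, beta (change per cycle), se,
#'   p_value, significant
#' @export
trend_regression <- function(density, demo,
                             metrics = c("sodium_mg_day", "sodium_per_gram",
                                         "sodium_per_kcal"),
                             by = NULL, cycle_levels = NULL, alpha = 0.01,
                             level = c("person", "cycle_mean"),
                             lonely = "error") {
  level <- match.arg(level)
  assert_columns(demo, c("person_id", "cycle", "stratum", "psu", "weight"),
                 "demographics")
  if (!is.null(by)) assert_columns(demo, by, "demographics")
  metrics <- match.arg(metrics, several.ok = TRUE)

  dat <- merge(density, demo, by = "person_id")
  cycle_levels <- cycle_levels %||% sort(unique(dat$cycle))
  if (length(cycle_levels) < 2L)
    fail("saltshift_domain_error", "trend_regression: need >= 2 cycles")
  dat$cycle_index <- match(dat$cycle, cycle_levels) - 1L
  if (anyNA(dat$cycle_index))
    fail("saltshift_domain_error", "trend_regression: cycle not in cycle_levels")
  dat$w_trend <- dat$weight / length(cycle_levels)

  dom_key <- if (is.null(by)) rep("(all)", nrow(dat)) else {
    interaction(dat[by], drop = TRUE, sep = "|")
  }
  res <- list()
  for (d in levels(factor(dom_key))) {
    sub <- dat[dom_key == d, , drop = FALSE]
    for (m in metrics) {
      if (level == "person") {
        X <- cbind(`(Intercept)` = 1, cycle_index = sub$cycle_index)
        fit <- svy_lm(X, sub[[m]], sub$w_trend, sub$stratum, sub$psu, lonely)
        beta <- fit$beta[2]; se <- fit$se[2]; df <- fit$df
      } else {
        cyc_mean <- vapply(seq_along(cycle_levels) - 1L, function(ci) {
          s2 <- sub[sub$cycle_index == ci, ]
          sum(s2$weight * s2[[m]]) / sum(s2$weight)
        }, numeric(1))
        ls <- stats::lm(cyc_mean ~ I(seq_along(cycle_levels) - 1L))
        beta <- stats::coef(ls)[2]
        se <- summary(ls)$coefficients[2, 2]
        df <- length(cycle_levels) - 2L
      }
      p <- if (is.finite(se) && se > 0) {
        2 * stats::pt(-abs(beta / se), df = max(df, 1L))
      } else if (abs(beta) < 1e-10) 1 else 0   # degenerate zero-variance fit
      row <- data.frame(metric = m, beta = beta, se = se, p_value = p,
                        significant = p < alpha, stringsAsFactors = FALSE)
      if (!is.null(by)) {
        doms <- strsplit(d, "|", fixed = TRUE)[[1]]
        for (i in seq_along(by)) row[[by[i]]] <- doms[i]
        row <- row[c(by, setdiff(names(row), by))]
      }
      res[[length(res) + 1L]] <- row
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
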