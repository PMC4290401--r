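# One-part (amount-only) usual-intake model for a nutrient consumed nearly
# every day.  Daily totals are Box-Cox transformed and modeled as
#   g(T_ij; lambda) = x_ij' beta + u_i + eps_ij,
# with a person-level random effect u_i ~ N(0, sigma2_between) and day-level
# noise eps_ij ~ N(0, sigma2_within).  Usual intake is the expectation of
# the back-transform over the day-noise distribution (and the person
# effect's conditional distribution), evaluated at reference covariates.

#' Box-Cox transform
#'
#' `(x^lambda - 1)/lambda` for `lambda > 0`; `log(x)` at `lambda = 0`.
#'
#' @param x positive numeric vector
#' @param lambda exponent in [0, 1]
#' @return transformed values
#' @export
boxcox <- function(x, lambda) {
  if (any(!is.finite(x) | x <= 0))
    fail("saltshift_domain_error", "boxcox: x must be positive")
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' Inverse Box-Cox transform
#'
#' `exp(y)` at `lambda = 0`, else `(lambda*y + 1)^(1/lambda)` with the
#' argument floored at zero so the back-transform is defined (and monotone
#' non-decreasing) on the whole real line.
#'
#' @param y numeric vector on the transformed scale
#' @param lambda exponent in [0, 1]
#' @return back-transformed values
#' @export
boxcox_inv <- function(y, lambda) {
  if (lambda == 0) exp(y) else pmax(lambda * y + 1, 0)^(1 / lambda)
}

# Person-day totals joined with demographics; one row per person-day.
person_day_totals <- function(recalls, demo) {
  assert_columns(recalls, c("person_id", "day", "sodium_mg", "weekend", "mode"),
                 "recalls")
  key <- paste(recalls$person_id, recalls$day, sep = "\r")
  ord <- !duplicated(key)
  pd <- data.frame(
    person_id = recalls$person_id[ord], day = recalls$day[ord],
    weekend = recalls$weekend[ord],
    telephone = recalls$mode[ord] == "telephone",
    stringsAsFactors = FALSE
  )
  pd$total_mg <- as.vector(tapply(recalls$sodium_mg, key, sum)[key[ord]])
  merge(pd, demo, by = "person_id")
}

amount_design_matrix <- function(formula, data, weekend, telephone) {
  # canonical factor levels so fit-time and prediction-time matrices share
  # columns even when a subset lacks some level
  canon <- list(age_group = age_group_levels(), gender = gender_levels(),
                ethnicity = ethnicity_levels())
  for (nm in intersect(names(canon), names(data))) {
    data[[nm]] <- factor(data[[nm]], levels = canon[[nm]])
  }
  X <- stats::model.matrix(formula, data)
  cbind(X, weekend = as.numeric(weekend), telephone = as.numeric(telephone))
}

#' Fit the one-part amount model
#'
#' The Box-Cox exponent is chosen on a grid by the profiled (weighted)
#' Gaussian likelihood including the Jacobian term.  Fixed effects are
#' estimated by survey-weight-scaled least squares; the within-person
#' variance comes from weighted squared half-differences of the two recall
#' days, and the between-person variance is the residual variance in excess
#' of it.  Weights are normalized to mean 1, so rescaling all weights by a
#' constant leaves every estimate unchanged.
#'
#' @param recalls validated recall table (food level)
#' @param demo demographics for the analysis population, with `age_group`
#'   (see [assign_age_groups()])
#' @param formula fixed-effect formula over person-level covariates; the
#'   weekend and interview-mode (telephone) indicators are always appended
#' @param lambda_grid candidate Box-Cox exponents
#' @param use_weights logical; use the survey weights (default TRUE)
#' @param weekend_frac,telephone_frac reference covariate values at which
#'   usual intake is evaluated: the long-run weekend frequency (default 3/7)
#'   and the telephone-interview frequency (default 0, i.e. the in-person
#'   day-1 reference)
#' @param n_quadrature Gauss-Hermite nodes for back-transformation
#' @return object of class `usual_intake_model`
#' @export
fit_amount_model <- function(recalls, demo,
                             formula = ~ age_group * gender * ethnicity,
                             lambda_grid = seq(0, 1, by = 0.05),
                             use_weights = TRUE,
                             weekend_frac = 3 / 7, telephone_frac = 0,
                             n_quadrature = 30L) {
  assert_columns(demo, c("person_id", "weight"), "demographics")
  pd <- person_day_totals(recalls, demo)
  if (any(pd$total_mg <= 0))
    fail("saltshift_domain_error",
         "fit_amount_model: non-positive day totals; filter them upstream")
  days_per_person <- table(pd$person_id)
  if (sum(days_per_person >= 2L) < 2L)
    fail("saltshift_identifiability_error",
         "fit_amount_model: need >= 2 persons with two recall days to identify the within-person variance")

  w <- if (use_weights) pd$weight else rep(1, nrow(pd))
  w <- w / mean(w)
  X <- amount_design_matrix(formula, pd, pd$weekend, pd$telephone)
  logT <- log(pd$total_mg)
  sum_w <- sum(w)

  profile_ll <- function(lambda) {
    y <- boxcox(pd$total_mg, lambda)
    fit <- stats::lm.wfit(X, y, w)
    sse <- sum(w * fit$residuals^2)
    -(sum_w / 2) * log(max(sse, 1e-300) / sum_w) + (lambda - 1) * sum(w * logT)
  }
  ll <- vapply(lambda_grid, profile_ll, numeric(1))
  lambda <- lambda_grid[which.max(ll)]

  y <- boxcox(pd$total_mg, lambda)
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0                     # aliased columns
  e <- as.vector(y - X %*% beta)

  # within-person variance from two-day half-differences
  two <- names(days_per_person)[days_per_person == 2L]
  idx2 <- as.character(pd$person_id) %in% two
  sub <- data.frame(pid = pd$person_id[idx2], day = pd$day[idx2],
                    e = e[idx2], w = w[idx2])
  sub <- sub[order(sub$pid, sub$day), ]
  d1 <- sub$e[sub$day == 1L]
  d2 <- sub$e[sub$day == 2L]
  wp <- (sub$w[sub$day == 1L] + sub$w[sub$day == 2L]) / 2
  sigma2_within <- sum(wp * (d1 - d2)^2 / 2) / sum(wp)

  # no residual-df correction: the moment estimator must be invariant to
  # duplicating records with proportionally downscaled weights
  p_eff <- sum(!is.na(fit$coefficients))
  n_obs <- nrow(pd)
  sigma2_total <- sum(w * e^2) / sum_w
  sigma2_between <- max(sigma2_total - sigma2_within, 0)

  structure(class = "usual_intake_model", list(
    lambda = lambda, beta = beta, colnames = colnames(X),
    sigma2_between = sigma2_between, sigma2_within = sigma2_within,
    formula = formula, use_weights = use_weights,
    weekend_frac = weekend_frac, telephone_frac = telephone_frac,
    n_quadrature = as.integer(n_quadrature),
    lambda_grid = lambda_grid, profile_ll = ll,
    residual_df = data.frame(n_obs = n_obs, p = p_eff)
  ))
}

#' @export
print.usual_intake_model <- function(x, ...) {
  cat(sprintf(
    "Usual-intake amount model: lambda = %.2f, sigma2_between = %.4f, sigma2_within = %.4f (%d day records)\n",
    x$lambda, x$sigma2_between, x$sigma2_within, x$residual_df$n_obs))
  invisible(x)
}

# Conditional (posterior) moments of the person effect given that person's
# residual mean over J days: shrinkage k = s2b/(s2b + s2w/J), conditional
# variance v = (1-k)*s2b.
conditional_person_effects <- function(model, pd_resid_mean, n_days) {
  s2b <- model$sigma2_between
  s2w <- model$sigma2_within
  if (s2w < 1e-12) {
    k <- rep(1, length(n_days))
  } else {
    k <- s2b / (s2b + s2w / n_days)
  }
  list(u_hat = k * pd_resid_mean, v = (1 - k) * s2b)
}

#' Per-person usual intake
#'
#' For each person, usual intake is the expectation of the inverse Box-Cox
#' transform of `x_ref' beta + u_i + eps`, where `x_ref` fixes the weekend
#' and telephone covariates at their reference fractions, `u_i` follows its
#' conditional normal distribution given the person's observed days
#' (shrunken mean, conditional variance), and `eps` is day noise.  The two
#' normal components are combined and integrated by Gauss-Hermite
#' quadrature; at `lambda = 0` this equals the lognormal closed form
#' `exp(mu_i + (v_i + sigma2_within)/2)`.
#'
#' @param model a fitted [fit_amount_model()]
#' @param recalls recall table (to recover each person's observed days)
#' @param demo demographics for the persons to evaluate
#' @return data.frame (person_id, usual_mg)
#' @export
usual_intake_per_person <- function(model, recalls, demo) {
  if (model$n_quadrature < 3L)
    fail("saltshift_config_error", "n_quadrature: need at least 3 nodes")
  pd <- person_day_totals(recalls, demo)
  X <- amount_design_matrix(model$formula, pd, pd$weekend, pd$telephone)
  X <- X[, model$colnames, drop = FALSE]
  e <- as.vector(boxcox(pd$total_mg, model$lambda) - X %*% model$beta)
  ebar <- tapply(e, pd$person_id, mean)
  ndays <- as.vector(table(pd$person_id)[names(ebar)])

  # reference design: one row per person, weekend/telephone at reference
  ids_chr <- names(ebar)
  demo_ord <- demo[match(ids_chr, as.character(demo$person_id)), , drop = FALSE]
  Xr <- amount_design_matrix(model$formula, demo_ord,
                             rep(model$weekend_frac, nrow(demo_ord)),
                             rep(model$telephone_frac, nrow(demo_ord)))
  Xr <- Xr[, model$colnames, drop = FALSE]
  mu_ref <- as.vector(Xr %*% model$beta)

  ce <- conditional_person_effects(model, as.vector(ebar), ndays)
  total_var <- ce$v + model$sigma2_within
  lambda <- model$lambda
  usual <- if (max(total_var) <= 1e-14) {
    boxcox_inv(mu_ref + ce$u_hat, lambda)
  } else {
    gh <- gauss_hermite(model$n_quadrature)
    out <- numeric(length(mu_ref))
    s <- sqrt(2 * total_var)
    for (kk in seq_along(gh$nodes)) {
      out <- out + gh$weights[kk] *
        boxcox_inv(mu_ref + ce$u_hat + s * gh$nodes[kk], lambda)
    }
    out / sqrt(pi)
  }
  data.frame(person_id = demo_ord$person_id, usual_mg = usual,
             stringsAsFactors = FALSE)
}

# Model-implied P(usual intake < t) for each person's covariate pattern:
# usual(u) = E_eps g^-1(x'beta + u + eps) is strictly increasing in u, so
# P(U < t) = Phi(u*/sigma_b) with usual(u*) = t.
prop_below_model <- function(model, mu_ref, thresholds) {
  s2b <- model$sigma2_between
  s2w <- model$sigma2_within
  lambda <- model$lambda
  gh <- gauss_hermite(model$n_quadrature)
  usual_at <- function(mu, u) {
    if (s2w <= 1e-14) return(boxcox_inv(mu + u, lambda))
    sum(gh$weights * boxcox_inv(mu + u + sqrt(2 * s2w) * gh$nodes, lambda)) /
      sqrt(pi)
  }
  sb <- sqrt(s2b)
  vapply(thresholds, function(t) {
    vapply(mu_ref, function(mu) {
      if (sb < 1e-8) return(as.numeric(usual_at(mu, 0) < t))
      lo <- -10 * sb; hi <- 10 * sb
      flo <- usual_at(mu, lo) - t
      fhi <- usual_at(mu, hi) - t
      if (flo >= 0) return(0)
      if (fhi <= 0) return(1)
      ustar <- stats::uniroot(function(u) usual_at(mu, u) - t, c(lo, hi),
                              tol = 1e-8)$root
      stats::pnorm(ustar / sb)
    }, numeric(1))
  }, numeric(length(mu_ref)))
}

#' Subgroup summary of per-person usual intakes
#'
#' Survey-weighted mean usual intake per reporting domain, with the
#' proportions of the subgroup's usual-intake distribution below the intake
#' thresholds.  Proportions are computed from the model-implied distribution
#' (the person effect integrated over the subgroup) and, for comparison,
#' from the empirical weighted fraction of per-person estimates below each
#' threshold.  Persons of ethnicity "Other" are retained in estimation but
#' excluded from reporting.
#'
#' @param intakes data.frame (person_id, usual_mg) from
#'   [usual_intake_per_person()]
#' @param demo demographics with `age_group` and the `by` columns
#' @param by domain columns (default age group x gender x ethnicity)
#' @param thresholds intake thresholds in mg/day (default 1500 and 2300)
#' @param model optional fitted model; needed for the model-implied
#'   proportions below thresholds
#' @return data.frame of domain rows: mean, n, and per-threshold proportions
#' @export
subgroup_summary <- function(intakes, demo,
                             by = c("age_group", "gender", "ethnicity"),
                             thresholds = c(1500, 2300), model = NULL) {
  assert_columns(demo, c("person_id", "weight", by), "demographics")
  dat <- merge(intakes, demo, by = "person_id")
  if ("ethnicity" %in% by) dat <- dat[dat$ethnicity %in% reported_ethnicities(), ]
  dom <- interaction(dat[by], drop = TRUE, sep = "|")

  mu_ref <- NULL
  if (!is.null(model)) {
    Xr <- amount_design_matrix(model$formula, dat,
                               rep(model$weekend_frac, nrow(dat)),
                               rep(model$telephone_frac, nrow(dat)))
    mu_ref <- as.vector(Xr[, model$colnames, drop = FALSE] %*% model$beta)
  }

  rows <- lapply(levels(dom), function(d) {
    idx <- dom == d
    w <- dat$weight[idx]
    row <- as.list(strsplit(d, "|", fixed = TRUE)[[1]])
    names(row) <- by
    row$mean <- sum(w * dat$usual_mg[idx]) / sum(w)
    row$n <- sum(idx)
    for (t in thresholds) {
      row[[sprintf("prop_below_%g_empirical", t)]] <-
        sum(w * (dat$usual_mg[idx] < t)) / sum(w)
    }
    if (!is.null(mu_ref)) {
      pb <- prop_below_model(model, mu_ref[idx], thresholds)
      pb <- matrix(pb, nrow = sum(idx))
      for (j in seq_along(thresholds)) {
        row[[sprintf("prop_below_%g", thresholds[j])]] <-
          sum(w * pb[, j]) / sum(w)
      }
    }
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Rao-Wu(-Yue) stratified PSU bootstrap replicate weights: within each
# stratum of n_h PSUs, draw n_h - 1 PSUs with replacement; a person's weight
# multiplier is (times their PSU was drawn) * n_h/(n_h - 1).
bootstrap_multipliers <- function(stratum, psu) {
  cl <- paste(stratum, psu, sep = "\r")
  mult <- numeric(length(cl))
  for (s in unique(stratum)) {
    idx <- stratum == s
    psus <- unique(cl[idx])
    nh <- length(psus)
    if (nh < 2L) { mult[idx] <- 1; next }
    draws <- sample(psus, nh - 1L, replace = TRUE)
    counts <- table(factor(draws, levels = psus))
    mult[idx] <- as.vector(counts[cl[idx]]) * nh / (nh - 1L)
  }
  mult
}

#' Estimate usual sodium intake by subgroup
#'
#' Runs the full estimation chain: fits the amount model, evaluates
#' per-person usual intakes, and summarises by domain with standard errors
#' from a stratified PSU bootstrap of the entire chain (PSUs resampled
#' within strata with Rao-Wu rescaling, model refitted, intakes and domain
#' means re-evaluated).  Domains whose persons span fewer than 2 PSUs get
#' `se = NA`.
#'
#' @param recalls validated recall table
#' @param demo filtered demographics with `age_group`
#' @param by domain columns
#' @param thresholds intake thresholds (mg/day)
#' @param bootstrap bootstrap replicates for SEs (0 skips SEs)
#' @param seed seed for the bootstrap resampling
#' @param ... passed to [fit_amount_model()]
#' @return list with `model`, `intakes` (per person) and `subgroups`
#'   (domain table with mean, se, n, proportions below thresholds)
#' @export
estimate_usual_intake <- function(recalls, demo,
                                  by = c("age_group", "gender", "ethnicity"),
                                  thresholds = c(1500, 2300),
                                  bootstrap = 200L, seed = 1L, ...) {
  model <- fit_amount_model(recalls, demo, ...)
  intakes <- usual_intake_per_person(model, recalls, demo)
  subgroups <- subgroup_summary(intakes, demo, by, thresholds, model)

  if (bootstrap > 0L) {
    reps <- with_seed(seed, {
      lapply(seq_len(bootstrap), function(b) {
        mult <- bootstrap_multipliers(demo$stratum, demo$psu)
        keep <- mult > 0
        demo_b <- demo[keep, , drop = FALSE]
        demo_b$weight <- demo_b$weight * mult[keep]
        rec_b <- recalls[recalls$person_id %in% demo_b$person_id, , drop = FALSE]
        m_b <- fit_amount_model(rec_b, demo_b, ...)
        i_b <- usual_intake_per_person(m_b, rec_b, demo_b)
        s_b <- subgroup_summary(i_b, demo_b, by, thresholds, model = NULL)
        s_b
      })
    })
    key0 <- do.call(paste, c(subgroups[by], sep = "|"))
    boot_means <- sapply(reps, function(s_b) {
      kb <- do.call(paste, c(s_b[by], sep = "|"))
      s_b$mean[match(key0, kb)]
    })
    subgroups$se <- apply(matrix(boot_means, nrow = length(key0)), 1,
                          stats::sd, na.rm = TRUE)
    # flag domains represented in < 2 PSUs
    dk <- do.call(paste, c(demo[by], sep = "|"))
    psu_per_dom <- tapply(paste(demo$stratum, demo$psu), dk,
                          function(x) length(unique(x)))
    subgroups$se[psu_per_dom[key0] < 2] <- NA_real_
    cols <- c(by, "mean", "se", setdiff(names(subgroups), c(by, "mean", "se")))
    subgroups <- subgroups[cols]
  }
  list(model = model, intakes = intakes, subgroups = subgroups)
}
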