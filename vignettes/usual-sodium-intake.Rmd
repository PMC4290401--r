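---
title: "Estimating usual sodium intake and modeling reformulation scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating usual sodium intake and modeling reformulation scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltshift)
```

## The problem

National nutrition surveillance asks three related questions about dietary
sodium: how much sodium do demographic subgroups *usually* consume, how has
intake (absolute and as a density of the diet) moved across survey cycles,
and how much could intake fall if a defined set of foods were reformulated
with less sodium.  The raw material is two 24-hour dietary recalls per
person (day 1 in person, day 2 by telephone) from a stratified multi-stage
survey such as NHANES, plus a food-code taxonomy (the nine top-level FNDDS
food groups) and sampling-design columns (stratum, PSU, weight).

A single recall day is a noisy measure of a person's long-run average
intake: day-to-day (within-person) variation is large, so the distribution
of one-day intakes is wider than the distribution of *usual* intakes, and
naive proportions below an intake threshold are badly biased.  saltshift
implements the standard remedy, a one-part (amount-only) measurement-error
model in the style of the National Cancer Institute method, appropriate for
sodium because essentially everyone consumes some sodium every day — no
consumption-probability part is needed.

## The amount model

Let \(T_{ij}\) be person \(i\)'s total sodium on recall day \(j \in \{1,2\}\).
With the Box–Cox transform \(g(t;\lambda) = (t^\lambda - 1)/\lambda\)
(\(\log t\) at \(\lambda = 0\)), the model is

\[
g(T_{ij};\lambda) = \mathbf{x}_{ij}'\boldsymbol\beta + u_i + \varepsilon_{ij},
\qquad
u_i \sim N(0, \sigma^2_b), \quad \varepsilon_{ij} \sim N(0, \sigma^2_w).
\]

The fixed effects \(\mathbf{x}_{ij}\) are the subgroup cells (age group
2–18 / 19–50 / 51+, crossed with gender and ethnicity) plus two recall-day
nuisance covariates: a weekend indicator and a day-2/telephone indicator.

Fitting proceeds in three steps:

1. **\(\lambda\) selection.**  \(\lambda\) is profiled over a coarse grid
   (default \(\{0, 0.05, \ldots, 1\}\)) by the weighted Gaussian likelihood
   including the Jacobian term
   \((\lambda - 1)\sum_{ij} w_i \log T_{ij}\).  A grid keeps the selection
   reproducible and removes a fragile inner optimisation.
2. **Fixed effects.**  Weighted least squares with the person's survey
   weight (normalised to mean 1) attached to both of their days — a
   pseudo-likelihood use of the design weights.
3. **Variance components.**  With at most two days per person, the
   within-person variance has a closed moment estimator from half squared
   differences of each person's two residuals,
   \(\hat\sigma^2_w = \sum_i w_i (e_{i1}-e_{i2})^2 / (2\sum_i w_i)\), and
   \(\hat\sigma^2_b\) is the total weighted residual variance in excess of
   it (floored at zero).  No residual-df correction is applied: the moment
   estimator is then exactly invariant to duplicating records with
   proportionally downscaled weights, which is also the contract the test
   suite enforces.

### Back-transformation and reference covariates

Usual intake is a *real-life* long-run mean, so the nuisance covariates are
set to reference values before back-transforming: the weekend indicator to
its long-run frequency (default 3/7) and the telephone indicator to 0 —
a telephone interview has no frequency in daily life; day 1 (in person) is
the reference mode.  Both are configurable.

For person \(i\), the conditional distribution of \(u_i\) given the
observed days is normal with shrunken mean
\(\hat u_i = k_i \bar e_i\), \(k_i = \sigma^2_b/(\sigma^2_b + \sigma^2_w/J_i)\),
and variance \(v_i = (1-k_i)\sigma^2_b\).  Usual intake is

\[
\hat U_i = E\left[g^{-1}\!\big(\mathbf{x}_{\mathrm{ref},i}'\boldsymbol\beta
    + s\big)\right], \qquad
s \sim N(\hat u_i,\; v_i + \sigma^2_w),
\]

computed by Gauss–Hermite quadrature (default 30 nodes; the λ = 0 case has
the lognormal closed form \(\exp(\mu_i + (v_i + \sigma^2_w)/2)\), which the
quadrature reproduces to < 1e-6 relative).  Integrating over the *full*
conditional distribution of \(u_i\) — not just plugging in \(\hat u_i\) —
is a deliberate choice: with a plug-in BLUP the convexity of the
back-transform biases subgroup means downward by a factor
\(\exp((k-1)\sigma^2_b/2)\) at \(\lambda = 0\), whereas including \(v_i\)
makes subgroup means exactly unbiased there.  Per-person values remain
shrunken toward the subgroup mean, as in any empirical-Bayes predictor, so
they are suited to aggregation, not to individual diagnosis.

Proportions below the 1500 and 2300 mg/day guideline thresholds are
computed from the model-implied usual-intake distribution: within a
covariate pattern, usual intake is strictly increasing in \(u\), so
\(P(U < t) = \Phi(u^*/\sigma_b)\) where \(u^*\) solves \(U(u^*) = t\)
(found by `uniroot`).  The empirical weighted fraction of per-person
estimates below \(t\) is also reported; the model-implied version is the
headline number because the empirical one inherits shrinkage.

## Survey design statistics

All descriptive estimates are Hajek weighted means.  Standard errors come
from two routes:

* **Taylor linearization** (`weighted_mean_se`, and clustered sandwich
  variance inside `trend_regression`) with the with-replacement first-stage
  approximation: PSU totals of linearized scores, variance
  \(\sum_h \frac{n_h}{n_h-1}\sum_k (z_{hk}-\bar z_h)^2\).  Single-PSU
  strata raise an error by default or can be collapsed into the adjacent
  stratum.
* **Stratified Rao–Wu PSU bootstrap** for the usual-intake chain and the
  scenario engine, because those estimators are nonlinear multi-stage
  pipelines: within each stratum of \(n_h\) PSUs, \(n_h - 1\) PSUs are
  drawn with replacement and weights are rescaled by
  \(\text{(times drawn)} \times n_h/(n_h-1)\); the *entire* chain (model
  fit, back-transformation, domain means) is recomputed per replicate
  (default 200, seeded).

Cross-cycle trends regress the person-level metric (mg/day, mg/g food,
mg/kcal — each a ratio of the person's 2-day means) on the cycle index
0, 1, 2, …, with weights divided by the number of cycles combined (the
standard multi-cycle convention; it cannot affect point estimates) and a
two-sided design-based Wald test at the surveillance significance level
0.01.  A cycle-level variant (regression on per-cycle weighted means) is
available; person-level is the default because it preserves the design
information.

## The scenario engine

A reformulation scenario is a food-code table of maximum reduction
fractions \(r_f\) (the packaged salt-microsphere scenario targets 953
foods: 17 milk foods at 20%, 304 meat/poultry/fish foods at 20–25%, 20 egg
foods at 25%, 30 legume/nut foods at 25%, 511 grain foods at 25%, 35
vegetable foods at 20–30%, 36 fats/oils/dressings foods at 25%; ranges are
expanded as an even sequence across the category) together with a global
reduction scaling \(s\) and a market penetration \(p\), both in [0, 1].

In the default expected-value mode each targeted record's sodium is scaled
by \(1 - r_f\, s\, p\): penetration acts as the expected fraction of the
marketplace adopting the reformulated product, which makes reported
reductions exactly linear in \(p\).  A stochastic-assignment mode instead
reformulates each targeted food code independently with probability
\(p\) (full cut \(r_f\,s\) when adopted); its mean total reduction
converges to the expected-value mode and is provided for sensitivity
analysis.  Grams and energy are never modified — reformulation replaces
salt, not food.

`run_scenario` re-fits the complete usual-intake model on the modified
recalls with identical settings (full re-estimation, not a scaling
shortcut: the transform is nonlinear, so per-food reductions do not pass
through the model as simple fractions), then reports per domain the mean
per-person reduction, current and post-reduction usual intake, and the
percent reduction *averaged over individuals* (each person's reduction
divided by their own baseline, then averaged — the ratio of domain means is
also emitted).  Per-group breakdowns re-run single-group sub-scenarios;
both the group's share of the total reduction and the reduction relative
to the group's observed sodium are reported, since published group-level
percentages have ambiguous denominators.

## The synthetic cohort generator

Real survey microdata cannot ship with a package, so every stage is
exercised against `generate_cohort()`, which emits NHANES-shaped
demographics, two-day food-level recalls and a per-person truth table from
a known log-scale model: person-day sodium is
\(\exp(\mu_{\text{cell}} + u_i + \beta_{\text{wk}} W + \beta_{\text{seq}} D_2
+ \varepsilon)\), partitioned over food records by a Dirichlet draw centred
on the configured nine-group composition, with per-record energy and mass
emitted from lognormal sodium-density ratios.  True usual intake is the
real-life expectation \(\exp(\mu + u_i + \sigma^2_w/2)\,
((1-p_{\text{wk}}) + p_{\text{wk}} e^{\beta_{\text{wk}}})\) — the
telephone effect, a survey artifact, is excluded.

The defaults are the package's fixed study conditions, chosen once to
mirror the contemporary US surveillance profile:

* subgroup log-means giving adult usual intakes of roughly 2.5–4.6 g/day,
  ordered males > females, 19–50 > other ages, Non-Hispanic White highest;
* \(\sigma_b = 0.25\), \(\sigma_w = 0.35\) on the log scale (within-person
  variance exceeding between-person variance, as recall data show);
* weekend effect +0.05, day-2/telephone effect −0.06 (log scale), weekend
  probability 3/7 — the weekend definition in public recall files is
  ambiguous (Fri–Sun vs Sat–Sun), so the frequency is a knob, not an
  assertion;
* group composition (Grain 40%, Meat 27%, Milk 9%, Vegetables 9%, Sugars &
  Beverages 8%, others small) reproducing the published pattern of grain +
  meat ≈ two thirds of sodium and the top four groups ≈ 85%;
* food-pool sizes per group such that the packaged 953-food scenario
  covers roughly 30% of the sodium in each targeted group — hence about
  29% of total sodium — which places full-penetration reductions in the
  published 6–8% band;
* 15 strata × 2 PSUs assigned round-robin, lognormal weights with CV 0.5
  independent of intake, a ~1% under-2 rate and ~2% pregnancy/lactation
  rate among women 15–49 so the exclusion filters have work to do;
* optional per-cycle shifts in the log mean and in the sodium-per-gram
  density, used to plant trends (e.g. −0.10 mg/g per cycle with flat
  mg/day).

What the generator does **not** emulate: NHANES's oversampling and
non-response adjustments (weights here are independent of intake, so
weighted and unweighted estimates coincide in expectation), cluster
correlation within PSUs, FNDDS recipe disaggregation, item non-response,
and any correlation between diet composition and demographics beyond the
planted subgroup means.  Passing parameter-recovery tests therefore shows
the estimators are correct under the model's own assumptions — it does not
validate the model against real dietary behaviour, and published national
point estimates are not reproducible from synthetic data (the packaged
reference table of scenario reductions is shipped for arithmetic
cross-checks only).

## Numerical choices and degenerate inputs

* Gauss–Hermite nodes via the Golub–Welsch eigen decomposition; 30 nodes
  default, results stable to < 1e-4 relative between 9 and 41 nodes.
* For \(\lambda > 0\) the back-transform argument is floored at zero, so
  quadrature tails cannot produce complex values; the back-transform stays
  monotone non-decreasing.
* \(\hat\sigma^2_w < 10^{-12}\) (noise-free data) short-circuits both the
  shrinkage (\(k_i = 1\)) and the quadrature, making usual intake exactly
  the back-transform of the conditional mean — the noise-free fixtures in
  the test suite rely on this being exact, not approximate.
* Aliased design-matrix columns (e.g. a weekend column that never varies)
  get coefficient 0 rather than NA.
* Ties in the λ grid resolve to the first (smallest) maximiser via
  `which.max`.
* Domains spanning fewer than two PSUs keep their point estimate but get
  `se = NA`.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run entirely on
generated data at sizes chosen to make Monte-Carlo noise small relative to
the tolerances they assert: cohorts of 2000 persons (20 replicates) for
parameter recovery, 1200–1500 persons across five cycles for trend
recovery, 500 simulations of 250-person cohorts for the type-I error of
the 0.01-level trend test, 50-seed property sweeps for the scenario
algebra, and 100 random small designs for the Taylor-linearization oracle
comparison.

## Known limitations

* The one-part model is for daily-consumed nutrients only; episodically
  consumed foods need a two-part model, which is out of scope.
* Between-person variance is homoscedastic across subgroups on the
  transformed scale; covariate-dependent variances are not modeled.
* The λ grid is coarse by design; if the truth lies between grid points
  the variance components absorb the difference on the transformed scale.
* Percent-below-threshold estimates depend on the normality of the person
  effect on the transformed scale — a model assumption, not a guarantee.
* The scenario engine models no behavioural response (compensatory eating,
  discretionary-salt use) and no reformulation cost.
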