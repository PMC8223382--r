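---
title: "Decomposing educational inequality in a binary child-health outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing educational inequality in a binary child-health outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqdecomp)
```

## The problem

In many low- and middle-income countries, children of mothers with no formal
education ("illiterate" in the dichotomy used here) experience different
rates of diarrhoeal disease than children of mothers with at least completed
primary education ("literate"). The package quantifies that inequality at
the country level and then asks the harder question: *how much of the gap is
attributable to measurable differences in the circumstances of the two
groups* — household wealth, sanitation, maternal age, birth history,
neighbourhood deprivation — *and how much remains unexplained*?

Two layers of analysis answer this:

1. an **inequality surface**: weighted group prevalences, risk differences
   (RD), z-tests, fixed- and random-effects meta-analysis across countries
   with \(I^2\), Mantel–Haenszel pooled odds ratios controlling for country,
   and a four-quadrant classification of countries by prevalence and
   direction of inequality;
2. a **nonlinear decomposition** of each flagged country's gap into
   compositional (explained) and structural (unexplained) parts, with
   per-factor contributions.

Everything is exercisable end-to-end on synthetic survey-structured data
with known generative truth, so every stage is testable without
access-restricted microdata.

## Notation and the decomposition model

Let \(Y \in \{0,1\}\) be the outcome (diarrhoea in the preceding two weeks),
\(J \in \{I, L\}\) the literacy group, \(X\) the row vector of dummy-coded
covariates, \(w\) the sampling weight, and \(\bar Y^J\) the weighted mean
outcome in group \(J\). The gap is \(\bar Y^{IL} = \bar Y^I - \bar Y^L\);
positive values mean the outcome is more prevalent among children of
illiterate mothers (*pro-illiterate* inequality).

For a linear model the Blinder–Oaxaca identity splits the gap exactly:

\[
\bar Y^I - \bar Y^L
 = \underbrace{(\bar X^I - \bar X^L)\,\hat\beta^I}_{\text{explained}}
 + \underbrace{\bar X^L (\hat\beta^I - \hat\beta^L)}_{\text{unexplained}} .
\]

`linear_boda()` implements this with weighted least squares per group; the
explained term is partitioned over factor blocks.

For a logit model \(\Pr(Y=1\mid X) = F(X\beta)\) with \(F\) the logistic
CDF, means of predictions are not predictions of means, so the linear
identity fails. The nonlinear extension evaluates the same idea at the
observation level:

\[
\bar Y^I - \bar Y^L =
\Big[\tfrac{1}{N}\textstyle\sum_i F(X_i^I \hat\beta^*) -
     \tfrac{1}{N}\sum_i F(X_i^L \hat\beta^*)\Big] + \text{remainder},
\]

with \(\hat\beta^*\) fit on the pooled sample. The contribution of one
factor is the change in the mean predicted probability when that factor's
columns in the group-L rows are replaced by the matched group-I rows'
values, holding already-replaced factors at their I values and the rest at
L values. Replacing factors one at a time telescopes: within a replication
the per-factor contributions sum *exactly* to the full-replacement mean
minus the no-replacement mean, and the package asserts this to 1e-10.

Three practical complications, and how `decompose()` handles them:

* **Unequal group sizes.** Observation-level replacement needs matched
  pairs. Each replication draws a random subsample of the larger group of
  the smaller group's size; both sides are then sorted by predicted
  probability under the pooled fit and paired by rank
  (`match_subsample()`), so like risk profiles are swapped into like.
* **Path dependence.** The contribution of a factor depends on the order of
  replacement. With `ordering = "random"` each replication draws a uniform
  permutation of the factors; averaging over replications removes the
  arbitrariness. For small factor counts the average provably converges to
  the exhaustive all-permutations (Shapley) value, and the test suite
  checks a 10,000-replication run against the exact 6-permutation average
  for three factors.
* **Weights.** Sampling weights enter every model fit and every mean. The
  base rows of the sequential replacement are group L's (or, when L is the
  larger group, its subsampled) rows; each row's weight rides along
  unmodified.

The defaults — pooled coefficients, random ordering, 10,000 replications,
sample weights — are the configuration a production analysis would use.
The reported per-factor standard error is the standard deviation of the
per-replication contributions: a descriptive Monte-Carlo uncertainty, not a
sampling-theory standard error.

Because explained and unexplained parts are signed, a single factor can
contribute more than +100% or less than −100% of the gap; such
contributions net out against others, and `percent_of_gap` deliberately
does not truncate them.

Two deliberate design choices where the method leaves room:

* The pooled fit excludes a group indicator by default (a single
  \(\hat\alpha^*, \hat\beta^*\) evaluates all mixed rows); including the
  indicator is available via `include_group_indicator = TRUE`, in which
  case its coefficient only shifts the unexplained remainder.
* Categorical factors are replaced as whole dummy blocks, never
  column-by-column: a factor's categories are one decision variable, and
  per-dummy replacement would create impossible covariate rows (e.g. a
  child simultaneously in two wealth quintiles).

### The linear limit as a cross-check

Running the engine with `link = "identity"` and group-I coefficients on a
linear-probability fit reproduces the Blinder–Oaxaca terms exactly (with
equal group sizes and unit weights, where the identity is exact). This
degenerate-link equivalence is asserted in the tests and pins the
sequential-replacement machinery to a closed form.

## The weighted logistic layer

`fit_weighted_logit()` maximizes the weighted Bernoulli log-likelihood by
iteratively reweighted least squares with step-halving. Convergence is
declared when the relative log-likelihood change falls below 1e-10 or the
maximum absolute score component below 1e-8, within 100 iterations; the
`converged` flag is honest and downstream code refuses unconverged fits.
The covariance is the inverse observed information at the optimum; no
design-based correction is applied by default, because only coefficient
point estimates enter the decomposition. Apparent complete separation
(a coefficient diverging past 30 on the logit scale) is a hard error naming
the offending column — a silent garbage fit would poison the decomposition —
with an optional ridge (`ridge = 1e-6`-scale) escape hatch. Model fit is
summarized the standard way: `wald_all_coefficients()` (quadratic form over
all non-intercept columns) and `likelihood_ratio_test()` against the
intercept-only model.

Group inequality per country is emitted on two scales: the crude OR from
the weighted 2×2 table (`country_effects()`) and the covariate-adjusted OR
from a weighted logit with a group indicator (`adjusted_group_or()`).

## Inequality statistics: formulas and conventions

* **Prevalence and variance.** \( \hat p = \sum w y / \sum w\), with the
  Kish effective sample size \(n_{\mathrm{eff}} = (\sum w)^2 / \sum w^2\)
  and \(\widehat{\mathrm{var}} = \hat p (1-\hat p)/n_{\mathrm{eff}}\). The
  survey's weight unevenness thus inflates uncertainty without requiring
  full linearization.
* **Risk difference.** \( \mathrm{RD} = \hat p_I - \hat p_L\), variance
  \(v_I + v_L\), reported per 1000 children.
* **Meta-analysis.** Fixed effect by inverse-variance weighting; Cochran's
  \(Q\); between-country variance \(\tau^2\) by DerSimonian–Laird,
  truncated at zero; random effect re-weighted by \(1/(v_k+\tau^2)\);
  \(I^2 = \max(0, 100\,(Q-\mathrm{df})/Q)\).
* **Mantel–Haenszel.** Pooled OR \(\sum_k a_k d_k/n_k \big/ \sum_k b_k
  c_k/n_k\) on Kish-effective per-country counts, CI from the
  Robins–Breslow–Greenland variance, and a Woolf-type \(Q\) homogeneity
  test of stratum log-ORs around the pooled value with \(\mathrm{df} =
  K-1\). Strata with an empty margin are dropped with a note; zero cells
  get a flagged 0.5 continuity correction (the MH point estimate itself
  tolerates zero cells).
* **Classification.** A country is *pro-illiterate* when its RD confidence
  interval lies strictly above zero, *pro-literate* when strictly below;
  crossing with overall prevalence above/below a threshold (default: the
  pooled prevalence) yields the four quadrants, with non-significant
  countries left unclassified. A country where one literacy group is empty
  (everyone literate, say) is marked not-computable and excluded from
  pooling rather than silently dropped.

## Neighbourhood socio-economic status

Children in the same survey cluster (primary sampling unit) share a
neighbourhood. For each cluster, the weighted proportions of children from
poor households (default: bottom two wealth quintiles, configurable) and of
children whose mother is not employed are computed; both are standardized
across clusters using weighted moments (cluster weight = total child
weight) and the first principal component of their 2×2 correlation matrix
is extracted, sign-oriented so a higher score means more deprivation.
Clusters are cut into five weight-balanced quintiles of the score, quintile
1 being the highest-SES fifth, ties broken by input order for determinism;
every child inherits its cluster's quintile as the `neighbourhood_ses`
factor. Choices worth flagging: the correlation (standardized) matrix is
used rather than the covariance because the two inputs are proportions on
like scales, and the weighted-moment standardization is a deliberate choice
— unweighted cluster moments would be equally defensible.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` + `generate_children()` produce a
country → cluster → child hierarchy with:

* cluster-level sampling weights (selection probability uniform in
  `selection_prob_range`, weight its reciprocal) — unequal weights without
  calibration or nonresponse machinery;
* cluster-level wealth composition tilts (log-linear in the wealth score,
  SD `wealth_cluster_sd` = 0.5 by default), so clusters are internally
  correlated the way real PSUs are;
* literacy driven by household wealth: \(\Pr(\text{illiterate}\mid
  \text{wealth}) = F(\mathrm{logit}(0.31) - 0.53\,s)\) with \(s\) the
  centered quintile score, reproducing the empirical pattern of roughly
  half the poorest quintile and one-eighth of the richest being illiterate,
  and about a third overall;
* a logistic outcome model with known coefficients over six categorical
  factors (wealth, maternal age, toilet type, residence, child age,
  employment). The `"pooled"` coefficient profile matches pooled-table
  prevalence contrasts; the `"high_inequality"` profile steepens the wealth
  and toilet gradients to the level of settings where wealth dominates the
  gap, and is the profile the constructed recovery scenarios start from;
* country intercepts calibrated by root finding so the plug-in expected
  prevalence equals `target_prevalence` (0.142 by default), with evenly
  spaced deterministic offsets (±0.3 on the logit scale) for between-country
  heterogeneity.

Deliberately absent: outcome-level random intercepts (cluster effects enter
only through wealth composition, keeping the outcome model exactly the
logit the decomposition assumes), DHS stratification codes, calibration
weighting, nonresponse, and continuous covariates. Passing tests on this
generator therefore demonstrates correctness of the estimators under the
assumed logit data-generating process and survey-like weighting — not
robustness to model misspecification or informative nonresponse in real
surveys.

### Constructed scenarios and the plug-in oracle

`make_gap_scenario(share, gap, base)` returns a configuration whose groups
differ *only* in the distributions of wealth (and toilet type, for
intermediate shares), exponentially tilted so that the expected gap equals
`gap` with about `share` of it carried by wealth. The tilts are found by
deterministic root finding on the plug-in expectation (enumeration over the
category product); the wealth–literacy gradient and the cluster tilt are
switched off in scenarios so the echoed truth yields *exact* expectations.
`expected_decomposition()` computes the population-level Shapley
contributions from the truth alone — true coefficients, exhaustive subsets,
no simulation, no estimated quantities — and is the independent oracle the
recovery tests compare against. Infeasible targets (a gap the covariate
effects cannot produce by composition alone) error with the achievable
range rather than returning a silently-missed target.

## Numerical choices and degenerate inputs

* Decomposition RNG: one master seed; each replication derives an
  independent substream for its ordering and subsample draws, so runs are
  reproducible and the replication loop is parallelizable in principle.
* All sorting is made deterministic by breaking ties on row order.
* `total_gap = 0` makes `percent_of_gap` undefined; it is reported as `NA`
  rather than infinity.
* Complete-case handling: rows with missing mandatory fields are excluded
  at read time with a logged tally (`attr(records, "n_excluded")`); no
  imputation.
* The weighted chi-square association test rescales the weighted
  contingency table to the unweighted \(n\) before applying Pearson's
  formula, keeping the nominal test size honest under weighting; expected
  cells below 1 set a warning flag.
* \(\tau^2\) is truncated at zero; with \(\tau^2 = 0\) the random effect
  equals the fixed effect exactly, and a single study returns itself.

## Problem sizes

The shipped analysis scripts simulate 8 countries × 50 clusters × 30
children (12,000 records) and decompose flagged countries with 1000
replications; the engine default of 10,000 replications is what a final
analysis would use. The acceptance checks run the identity suite on 50
random datasets of 100–2,000 records per group with 2–6 factors, the
ordering oracle at 10,000 replications on 200 + 200 records, and the
recovery scenarios at 50,000 children per literacy group with 60
replications — sizes at which Monte-Carlo error is small relative to the
tolerances being asserted while a full run stays comfortably interactive.

## Using real survey extracts

The package reads any child-level CSV honouring the column contract; for
DHS child-recode files, `inst/extdata/dhs_recode_mapping.csv` documents the
variable-by-variable recode (source variable, rule, target category) that
produces such a CSV, and the README shows the command sequence. The
microdata themselves are registration-gated and are not shipped; nothing in
the test suite depends on them.

## Known limitations

* The unexplained component is reported only as a remainder; no
  coefficient-side detailed decomposition is attempted.
* Contribution standard errors are replication SDs, not design-based.
* The RD variance formula (Kish effective n) is a pragmatic design-aware
  approximation, not full Taylor linearization of the survey design.
* Random-ordering averaging removes path dependence in the mean but
  individual replications remain order-dependent by construction.
* The classification quadrants depend on the prevalence threshold; the
  default (pooled prevalence) is a convention, and `prevalence_threshold`
  should be set explicitly when comparing against published groupings.
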