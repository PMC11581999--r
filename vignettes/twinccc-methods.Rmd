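---
title: "Modelling smoking initiation and quantity in twin cohorts with twinccc"
author: "twinccc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling smoking initiation and quantity in twin cohorts with twinccc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinccc)
```

## The scientific problem

Smoking behaviour in a population is shaped jointly by age, sex, birth
cohort, and the genetic and environmental variation underlying individual
differences.  Twin cohorts make it possible to separate these strands:
monozygotic (MZ) co-twins share all of their segregating genes, dizygotic
(DZ) co-twins on average half of them, so the MZ/DZ contrast identifies
additive-genetic (A), shared-environmental (C) and unique-environmental (E)
variance components.  `twinccc` implements the two complementary analyses
used to study sex and cohort effects on tobacco consumption in a cohort of
same-sex adult twins born 1880--1957 and surveyed up to four times (1975,
1981, 1990, 2011):

1. a **causal--contingent--common (CCC) twin model** of the initiation of
   regular smoking (binary, liability-threshold) and the daily cigarette
   quantity of those who initiated (contingent, quasi-continuous), fitted
   simultaneously to four sex-by-cohort groups with equality constraints
   tested by likelihood ratio; and
2. a **three-level linear mixed model** of cigarette quantity across age
   (repeated measures nested in individuals nested in twin pairs).

Because the motivating registry data are not public, the package ships a
synthetic twin-cohort generator with the same statistical structure, so
that every stage — data preparation, descriptives, model fitting, model
comparison — is exercised end to end and validated by simulation.

## The CCC model

For one twin pair, the model places a 4-variate normal distribution on
$(L_1, Q_1, L_2, Q_2)$, where $L_i$ is twin $i$'s latent liability to
initiate regular smoking and $Q_i$ the latent quantity score:

* $\operatorname{Var}(L) = A + C + E = 1$.  Binary data cannot identify
  the liability variance, so it is fixed to 1 in every group; group
  differences in "amount of variation" are carried entirely by the
  quantity side, and threshold comparisons across groups are meaningful
  on this common scale.
* Twin $i$ initiates iff $L_i \ge \tau(\text{age}_i)$ with
  $\tau(\text{age}) = \tau_0 + \tau_{\text{age}}(\text{age} - 60)$.  Age
  moderation sits on the threshold (equivalently, on the liability mean
  with opposite sign); the reference age of 60 makes $\tau_0$ the
  predicted threshold at age 60, and $\tau_0 + 5\tau_{\text{age}}$ the
  predicted threshold at 65 — the two ages at which groups are compared.
* $Q_i = \mu(\text{age}_i) + b\,L_i + A_q + C_q + E_q$ deviates: the
  causal path $b$ carries initiation liability into quantity, and the
  quantity-specific ACE components describe variation in quantity
  independent of initiation.  Total quantity variance is
  $b^2\operatorname{Var}(L) + A_q + C_q + E_q$.
* Cross-twin covariances follow the standard twin algebra with additive
  genetic correlation 1 (MZ) or 0.5 (DZ) and shared-environment
  correlation 1 (`build_covariance()` reproduces it exactly).

The **direct symmetric parameterization** estimates variance components
directly (not as squared paths), allowing individually negative estimates;
only $E_q$ is kept positive (log scale) so the quantity distribution stays
proper.  This keeps likelihood-ratio tests unbiased near zero components.

### Full-information likelihood

Quantity is observed only for initiators ("individuals who do not initiate
carry no information on progression"), so each pair contributes the exact
probability of its observation pattern (`pair_loglik()`):

* (no, no): a bivariate-normal orthant probability;
* (yes with $q$, no): the marginal normal density of $q$ times the
  conditional orthant probability of the two initiation statuses given
  $Q_1 = q$;
* (yes with $q_1$, yes with $q_2$): the bivariate density of the
  quantities times the conditional orthant of both exceedances;
* initiators with missing quantity have the quantity integrated out;
  a co-twin with missing initiation status is marginalised, leaving the
  univariate analogue for the observed twin.

Bivariate-normal orthant probabilities are computed by a compiled
implementation of Genz's hybrid quadrature (`pbvn()`), accurate to about
1e-15 — far inside the 1e-7 contract the likelihood requires — and
validated in the tests against adaptive quadrature and an independent
library routine.  The whole pattern-wise likelihood is validated against
nested-quadrature oracles on random parameter sets.

### Quantity as a continuous score

The model consumes quantity as a quasi-continuous score: in simulation
studies the continuous latent score of initiators; for roster data the
1--8 ordinal category index (1 = none, 2 = under 5, ..., 8 = over 40
cigarettes/day).  An ordinal-threshold quantity model is deliberately out
of scope; treating the index as numeric mirrors modelling the *mean*
quantity corrected for age.  Whether the original analyses transformed the
index is not documented; the recovery experiments are internally
consistent because generator and fitter share one convention.

## Multigroup fitting, constraints and comparisons

`fit_multigroup()` minimises the summed deviance over four sex-by-cohort
groups (earlier cohort born 1901--1920 assessed 1975; later cohort born
1945--1957 assessed 2011; by sex).  Two interchangeable free-parameter
scales are available, each with 10 parameters per group:

* `"components"` — $A, C$ (initiation; $E = 1 - A - C$), $b$, $A_q, C_q,
  \log E_q$, $\tau_0, \tau_{\text{age}}, \mu_0, \mu_{\text{age}}$: natural
  for recovery experiments and profile intervals on the components
  themselves.
* `"levels"` — thresholds and means *at ages 60 and 65*, the standardized
  quantity-specific proportions, and a log variance amount (either the
  specific variance or the total quantity variance).  On this scale every
  comparison in the ladder — thresholds at 60/65, mean quantity at 60/65,
  causal path, initiation decomposition (6 df under the sum-to-one
  identification), quantity-specific decomposition, amount of specific
  variance, total variance — is a plain equality constraint implemented by
  parameter sharing, so degrees of freedom are counted transparently.

Unconstrained multigroup fits decompose into independent 10-parameter
blocks.  A single shared parameter is handled by nested (profile)
optimisation — an outer one-dimensional search over the shared value with
warm-started inner group refits — which avoids the slow zig-zag of
coordinate descent on coupled ridges; specs with several shared
parameters use a scaled joint quasi-Newton fit.  All fits use seeded
multi-start (default 5 jittered starts), report the optimizer code and the
scaled gradient sup-norm (converged when at most 1e-4), and never return a
silent estimate when every start fails.

`run_comparison_suite()` executes the omnibus-then-pairwise ladder: each
quantity of interest is first constrained to equality across all four
groups; when the omnibus test rejects at $\alpha = 0.05$, the four
meaningful two-group follow-ups (sex within cohort, cohort within sex)
locate the source.  p-values are plain chi-square; no boundary-mixture
correction is applied, matching the direct symmetric convention.

Profile-likelihood intervals (`profile_ci()`) bisect the profile deviance
to the $\chi^2_1$ 95% critical rise (3.841), with tolerance 1e-3 on the
parameter scale, at most 60 iterations per side, a search box of 6 Wald
standard errors by default, and explicit flags for open bounds (rise not
reached inside the box) and non-monotone profiles.

## The trajectory model

`fit_lmm()` fits, by maximum likelihood (so likelihood-ratio comparisons
remain valid),

$$y_{ijk} = \beta_0 + \beta_c\,\text{cohort} + \beta_s\,\text{sex}
  + \beta_a\,\text{age} + \beta_{a^2}\,\text{age}^2 + \beta_e\,\text{edu}
  + \beta_{sc}\,\text{sex}\times\text{cohort}
  + \beta_{ac}\,\text{age}\times\text{cohort}
  + u_{\text{pair}} + u_{\text{individual}} + \varepsilon,$$

with measures $k$ in individuals $j$ in pairs $i$, estimated via
`lme4::lmer`.  Coding conventions (shared by generator and fitter):
cohort is the numeric band index 1..7 (1880--1900 grouped, then 10-year
bands to 1951--1957), sex is male 0 / female 1 (a negative sex coefficient
then means males consume more), age is uncentred in years, education in
years.  The outcome is the 1--8 quantity index treated as numeric,
including never-regular individuals at "none"; a data subset excluding
them can equally be fitted, as the model makes no structural assumption
about them.  `marginal_r2()` reports the variance of the fixed predictor
over total variance; `predict_trajectory()` evaluates the quadratic
age-profile and its vertex (peak) age
$-(\beta_a + \beta_{ac}\,\text{cohort})/(2\beta_{a^2})$, which under the
published coefficients increases across cohorts (about 34 years in the
earliest band).

## The synthetic cohort generator

`simulate_twin_cohort()` draws same-sex MZ and DZ pairs under the CCC
generative structure and emits a roster in the long per-assessment layout.
What it emulates, and the calibration choices behind the defaults:

* **Demographics.**  The earlier supergroup is assessed in 1975, 60%
  female, with age drawn from a truncated normal, mean 62.9, SD 5.3, on
  55--75; the later supergroup is assessed in 2011, 51% female, age 60.3
  (3.8) on 53--67.  A truncated normal was chosen over a uniform draw so
  the simulated mean age tracks the reported one (truncation shifts the
  realised mean by roughly +0.6 years in the earlier cohort, which the
  tests allow for).  Birth years are clamped to the study domain
  1880--1957, and co-twins share birth year, sex and zygosity.  The MZ:DZ
  ratio defaults to 1:2.
* **Initiation and quantity.**  Liability is an ACE-structured standard
  normal (defaults A = 0.5, C = 0.2, E = 0.3, in line with the reference
  parameter set used throughout the tests); the quantity-specific
  decomposition defaults to h² = 0.40, c² = 0.02, e² = 0.58, matching the
  reported pattern of roughly 0.4/0.6 with minimal shared environment.
  Group thresholds, mean quantities, specific-variance amounts and causal
  paths default to values reproducing the reported *orderings*: highest
  threshold and steepest threshold-age slope for later-cohort males,
  higher means and larger specific variance in males, largest total
  quantity variance in later-cohort males, and an attenuated causal path
  in earlier-cohort males.  The magnitudes are calibration choices, not
  published facts.
* **Items.**  The ever-smoking item is generated from the same liability
  with a threshold 0.6 below the regular-smoking threshold, giving the
  never / ever-only / regular split used in prevalence figures.  The
  latent quantity of initiators is discretised onto the 8-category scale
  by unit-spaced cut points from 1.5 to 7.5, placing the male-typical
  mode near the 20--24 band; no marginal category distribution is
  published, so these cut points are configuration constants.  Education
  is truncated normal, mean 10, SD 3, floor 4 years — its scale is never
  described in the source material, so years is an assumption.
* **What is not modelled.**  Mortality and attrition between waves,
  opposite-sex pairs, and item-level measurement error (an optional
  missing-at-random item rate is available but defaults to 0).  Passing
  tests therefore demonstrate correctness of the machinery under the
  stated generative structure, not robustness to informative dropout or
  misreported items in real data.

`simulate_longitudinal_quantity()` generates the repeated-measures table
for the trajectory model: pairs with uniform birth years 1880--1957,
rows for every wave at which age falls in 18--95, outcome = fixed-effect
predictor + pair intercept + individual intercept + residual.  With the
published fixed effects as generating coefficients the fixed predictor has
variance about 0.93 on this design; the default variance components
(pair 1.15, individual 2.29, residual 2.29 — a 1:2:2 split) are calibrated
so the fixed effects explain 14% of the outcome variance, the reported
marginal R².

## Numerical choices and problem sizes

* Orthant probabilities: compiled Genz quadrature, absolute error below
  1e-7 by a wide margin; degenerate correlations (±1) fall back to the
  comonotone closed forms.
* Non-positive-definite implied covariances yield a deviance penalty
  (likelihood $-\infty$), never a crash; equality constraints that map
  starting values into an invalid region (e.g. a shared total variance
  below one group's $b^2$) are repaired by blending toward moment-based
  starts, with the causal path severed as a last resort.
* Identical quantity-free observation patterns are aggregated with
  weights, so optimisation cost scales with the number of distinct
  configurations rather than the number of concordant-nonsmoking pairs.
* The tetrachoric correlation uses the two-step estimator (thresholds at
  the marginal normal quantiles, one-dimensional likelihood maximisation
  over the correlation): standard and stable on small tables.  Perfectly
  concordant tables return ±1 exactly; an empty margin returns `NA`.
* Simulation-based validation sizes, chosen to keep the full suite within
  a routine test run while retaining power: parameter recovery at 4000
  pairs per zygosity per group with 20 replicates (bias of the key
  parameters below 0.05) and rotating profile-interval coverage;
  likelihood-ratio calibration at 100 pairs per zygosity per group with
  200 replicates (omnibus rejection between 2% and 9% at the 5% level);
  trajectory recovery at 3000 pairs with 5 replicates in the tests and 20
  in the acceptance script.

## Known limitations

* The quantity score is treated as Gaussian; heavy discretisation at the
  scale ends is not modelled (no cumulative-link variant).
* Initiation liability variance is fixed to 1 per group; if the original
  analyses fixed it in a reference group only, threshold levels would
  shift but threshold *comparisons* would be unaffected.
* Degrees of freedom for the reported ladder are derived from the
  constraint structure; the source tables do not state them, so recorded
  df are the package's own accounting.
* No survey weighting, imputation, dominance components, or relative
  classes beyond MZ/DZ same-sex pairs.
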