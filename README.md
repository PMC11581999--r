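# twinccc

Causal–contingent–common (CCC) twin models and longitudinal mixed models
for studying sex and birth-cohort effects on tobacco consumption in
same-sex twin cohorts.

## What problem this package addresses

Smoking has two coupled phenotypes with very different measurement
properties: whether a person ever became a regular smoker (binary, and
best modelled as a liability-threshold trait), and how much they smoked
when they did (observed only for initiators, on an 8-category daily-
quantity scale).  Twin data — monozygotic (MZ) pairs sharing all their
segregating genes, dizygotic (DZ) pairs on average half — let both traits
be decomposed into additive-genetic (A), shared-environment (C) and
unique-environment (E) variance, and let the dependence of quantity on
initiation be estimated even though non-initiators carry no quantity
information.  `twinccc` is for biostatisticians and behaviour-genetics
researchers who want that analysis as tested, scriptable code:

* the **CCC model**: a 4-variate normal latent model per twin pair
  `(L1, Q1, L2, Q2)` with unit-variance initiation liability `L`,
  age-moderated threshold `τ(age) = τ0 + τ_age·(age − 60)`, a causal path
  `b` from liability to quantity, quantity-specific ACE components, and
  age-moderated quantity mean — fitted by full-information maximum
  likelihood over every observation pattern (concordant/discordant
  initiation, observed/missing quantity, singleton twins);
* **multigroup machinery**: four sex × cohort groups fitted
  simultaneously, equality constraints by parameter sharing,
  likelihood-ratio tests (omnibus across all groups, then pairwise
  follow-ups), and profile-likelihood confidence intervals;
* a **three-level linear mixed model** of quantity across age
  (measures in individuals in pairs; fixed effects for cohort, sex,
  age, age², education, sex×cohort, age×cohort) via `lme4`, with
  marginal R² and predicted trajectories including the peak age
  `−(β_age + β_age×cohort·cohort)/(2·β_age²)`;
* **descriptives**: lifetime smoking variables collapsed across up to
  four survey waves, 10-year birth-cohort bands (1880–1900 grouped),
  prevalence tables by sex × cohort, twin concordances and tetrachoric
  correlations;
* a **synthetic twin-cohort generator** emulating a Finnish-style cohort
  of same-sex twins born 1880–1957 (the motivating registry data are not
  publicly available), so the entire pipeline is reproducible and
  testable offline.

## A worked example

Simulate the "earlier" supergroup (assessed 1975, born 1901–1920), build
analysis-ready pairs, inspect twin similarity, and fit the CCC model to
both sexes:

```r
library(twinccc)

spec   <- cohort_sim_spec("earlier", n_pairs_per_zygosity = c(MZ = 1000, DZ = 2000))
roster <- simulate_twin_cohort(spec, seed = 42)
pairs  <- pair_observations_from_roster(roster)

twin_concordance_and_correlation(pairs)
#>            group zygosity n_pairs concordance tetrachoric quantity_r
#> 1 earlier-female       MZ     618   0.4898649   0.6795989  0.4476748
#> 2 earlier-female       DZ    1213   0.3534884   0.3984973  0.2175286
#> 3   earlier-male       MZ     372   0.5411765   0.7615922  0.4230446
#> 4   earlier-male       DZ     774   0.3916256   0.4802918  0.2078445
```

MZ pairs are clearly more similar than DZ pairs on both traits — the
signature of additive-genetic variance (the generator's initiation
decomposition is A = 0.5, C = 0.2, so the expected MZ/DZ latent
correlations are 0.7 and 0.45).

```r
fit <- fit_multigroup(pairs,
                      ccc_model_spec(c("earlier-female", "earlier-male"),
                                     "components"),
                      control = list(n_starts = 2))
fit
#> Multigroup CCC fit (components parameterization)
#>   -2 lnL = 13626.250 with 20 free parameters; converged
#> group earlier-female (1831 pairs):
#>   initiation ACE: A=0.562 C=0.118 E=0.320
#>   causal path b=0.301; quantity ACE: A=0.471 C=-0.033 E=0.555
#>   threshold: 0.353 +0.0023/yr; quantity mean: 4.871 -0.0155/yr
#> ...

unlist(standardize_components(fit$estimates[["earlier-male"]]))[c("h2_q", "e2_q")]
#>      h2_q      e2_q
#> 0.3897489 0.5977789
```

Here quantity is the 1–8 category index, so `b` and the variance amounts
are on the category scale; the standardized quantity-specific
decomposition (h²_q ≈ 0.39, e²_q ≈ 0.60 above) recovers the generator's
0.40/0.58 with minimal shared environment.  `run_comparison_suite(pairs)`
runs the full omnibus-then-pairwise ladder (thresholds and mean quantity
at ages 60 and 65, causal path, both ACE decompositions, variance
amounts); `profile_ci()` gives profile-likelihood intervals.

The longitudinal side:

```r
d   <- simulate_longitudinal_quantity(3000, trajectory_parameters(), seed = 7)
lmm <- fit_lmm(d)
lmm
#> Three-level mixed model of quantity (ML)
#>                 estimate      se         t
#> beta_intercept   6.50200 0.64388  10.09813
#> beta_cohort     -0.24702 0.08445  -2.92493
#> beta_sex        -1.53127 0.11898 -12.86946
#> beta_age         0.03884 0.01367   2.84122
#> beta_age2       -0.00069 0.00007  -9.58733
#> ...
#> marginal R2 = 0.140 on 19378 observations
```

The generating coefficients are the published fixed-effect estimates
(sex −1.67, cohort −0.22, age 0.05, age² −7.6×10⁻⁴); the fit recovers
them within sampling error, and the fixed effects explain 14% of the
outcome variance by calibration of the generator's variance components.

A thin CLI over the same functions lives at `inst/cli/twinccc`
(`simulate`, `describe`, `fit-ccc`, `fit-lmm`, `compare`, `validate`,
`run-all`), and `run_pipeline()` orchestrates the whole run with one root
seed and a manifest.

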