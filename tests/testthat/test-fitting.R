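fake_fit <- function(m2ll, n_free, groups = ccc_groups) {
  structure(list(minus2LL = m2ll, n_free = n_free,
                 spec = list(groups = groups)), class = "ccc_fit")
}

test_that("equality constraints reduce the free-parameter count by groups minus one", {
  spec <- ccc_model_spec(parameterization = "components")
  expect_equal(twinccc:::n_free_params(spec), 40)
  # omnibus on the causal path: 3 degrees of freedom
  expect_equal(twinccc:::n_free_params(constrain(spec, "b")), 37)
  # equating the initiation decomposition across all four groups costs
  # 2 x 3 = 6 under the A + C + E = 1 identification
  s2 <- constrain(constrain(spec, "A_init"), "C_init")
  expect_equal(twinccc:::n_free_params(s2), 34)
  # a one-group constraint is a no-op
  expect_identical(constrain(spec, "b", "later-male"), spec)
  expect_error(constrain(spec, "banana"), "unknown parameter")
  expect_error(constrain(spec, "b", c("later-male", "cats")),
               "unknown group")
  expect_error(constrain(constrain(spec, "b"), "b",
                         c("later-male", "later-female")),
               "already constrained")
  # levels-scale parameters exist only in the levels parameterization
  expect_error(constrain(spec, "t60"), "unknown parameter")
  expect_equal(twinccc:::n_free_params(
    constrain(ccc_model_spec(parameterization = "levels"), "t60")), 37)
})

test_that("likelihood-ratio tests follow the chi-square reference", {
  # identical fits: no evidence
  cmp <- lrt(fake_fit(1000, 40), fake_fit(1000, 37))
  expect_equal(cmp$delta_minus2LL, 0)
  expect_equal(cmp$p_value, 1)
  # the textbook 3.841 / 1 df boundary sits at p = 0.05
  cmp2 <- lrt(fake_fit(1000, 40), fake_fit(1003.841, 39))
  expect_equal(cmp2$df, 1)
  expect_equal(cmp2$p_value, 0.05, tolerance = 1e-3)
  # tiny negative noise is clamped; real reversals are errors
  expect_equal(lrt(fake_fit(1000, 40),
                   fake_fit(1000 - 1e-8, 39))$delta_minus2LL, 0)
  expect_error(lrt(fake_fit(1000, 40), fake_fit(999, 39)),
               "optimization failure")
  expect_error(lrt(fake_fit(1000, 40), fake_fit(1001, 40)), "df")
  expect_error(lrt(fake_fit(1000, 40),
                   fake_fit(1001, 39, groups = "earlier-male")),
               "not nested")
})

test_that("multigroup estimates recover moderate-sample generating values", {
  pairs <- simulate_ccc_study(800, equal_group_params(), seed = 41)
  fit <- fit_multigroup(pairs, ccc_model_spec(parameterization =
                                                "components"),
                        control = list(n_starts = 2))
  expect_true(fit$converged)
  expect_equal(fit$n_free, 40)
  truth <- ref_params()
  for (g in ccc_groups) {
    est <- fit$estimates[[g]]
    expect_lt(abs(est$b - truth$b), 1.0)       # ~3 SE at this sample size
    expect_lt(abs(est$tau0 - truth$tau0), 0.15)
    expect_lt(abs(est$mu0 - truth$mu0), 0.5)
    expect_lt(abs(est$E_q - truth$E_q), 0.4)
  }
  # estimates pooled over groups sharpen the causal-path recovery
  bbar <- mean(vapply(fit$estimates, `[[`, 0, "b"))
  expect_lt(abs(bbar - truth$b), 0.4)
  expect_error(fit_multigroup(pairs[pairs$group != "later-male", ],
                              ccc_model_spec()), "later-male")
})

test_that("estimates are invariant to relabeling twin one and twin two", {
  pairs <- simulate_ccc_study(400, seed = 42)
  swapped <- pairs
  swapped[, c("age1", "age2", "init1", "init2", "q1", "q2")] <-
    pairs[, c("age2", "age1", "init2", "init1", "q2", "q1")]
  spec <- ccc_model_spec(parameterization = "components")
  f1 <- fit_multigroup(pairs, spec, control = list(n_starts = 1,
                                                   hessian = FALSE))
  f2 <- fit_multigroup(pair_observations(swapped), spec,
                       control = list(n_starts = 1, hessian = FALSE))
  expect_equal(f1$minus2LL, f2$minus2LL, tolerance = 1e-8)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-5)
})

test_that("profile bisection solves an exact quadratic deviance", {
  # on a quadratic surface the 3.841 crossing is est +/- 1.96 SE
  se <- 0.37
  est <- 1.2
  pf <- function(v) 500 + ((v - est) / se)^2
  crit <- qchisq(0.95, 1)
  lo <- twinccc:::profile_side(pf, est, est - 6 * se, 500 + crit, 500,
                               1e-4, 60)
  hi <- twinccc:::profile_side(pf, est, est + 6 * se, 500 + crit, 500,
                               1e-4, 60)
  expect_equal(lo$value, est - qnorm(0.975) * se, tolerance = 1e-3)
  expect_equal(hi$value, est + qnorm(0.975) * se, tolerance = 1e-3)
  expect_equal(c(lo$flag, hi$flag), c("converged", "converged"))
  # a bound outside the search box is reported open
  op <- twinccc:::profile_side(pf, est, est + 0.5 * se, 500 + crit, 500,
                               1e-4, 60)
  expect_identical(op$flag, "open")
  expect_true(is.na(op$value))
})

test_that("profile intervals bracket the estimate and flag open bounds", {
  pairs <- simulate_ccc_study(800, seed = 43)
  d <- pairs[pairs$group == "earlier-female", ]
  spec <- ccc_model_spec("earlier-female", parameterization = "components")
  fit <- fit_multigroup(d, spec, control = list(n_starts = 1))
  ci <- profile_ci(d, spec, fit, "earlier-female|mu0")
  expect_lt(ci$lower, fit$estimates[["earlier-female"]]$mu0)
  expect_gt(ci$upper, fit$estimates[["earlier-female"]]$mu0)
  # the 95% profile interval approximates the Wald interval at this n
  se <- fit$se[["earlier-female|mu0"]]
  expect_equal(ci$upper - ci$lower, 2 * qnorm(0.975) * se,
               tolerance = 0.2)
  tiny <- profile_ci(d, spec, fit, "earlier-female|mu0", box = 0.01)
  expect_identical(unname(tiny$flags), c("open", "open"))
  expect_error(profile_ci(d, spec, fit, "earlier-female|nope"),
               "unknown parameter")
})

test_that("a null causal path is covered by its interval", {
  gp <- equal_group_params(ref_params(b = 0))
  pairs <- simulate_ccc_study(600, gp, seed = 44)
  d <- pairs[pairs$group == "earlier-male", ]
  spec <- ccc_model_spec("earlier-male", parameterization = "components")
  fit <- fit_multigroup(d, spec, control = list(n_starts = 1))
  ci <- profile_ci(d, spec, fit, "earlier-male|b")
  expect_lt(ci$lower, 0)
  expect_gt(ci$upper, 0)
})

test_that("constrained fits stay above the full fit and follow nesting order", {
  pairs <- simulate_ccc_study(250, seed = 45)
  data <- twinccc:::ccc_prepare(pairs)
  spec <- ccc_model_spec(parameterization = "levels")
  full <- fit_multigroup(data, spec, control = list(n_starts = 1,
                                                    hessian = FALSE))
  for (pm in c("b", "t60", "m65")) {
    cs <- constrain(spec, pm)
    red <- fit_multigroup(data, cs,
                          starts = constrained_starts(full, cs),
                          control = list(n_starts = 1, hessian = FALSE))
    cmp <- lrt(full, red)
    expect_gte(cmp$delta_minus2LL, 0)
    expect_equal(cmp$df, 3)
    expect_gte(cmp$p_value, 0)
    expect_lte(cmp$p_value, 1)
  }
})

test_that("the comparison ladder runs omnibus tests and locates group differences", {
  # later-male total quantity variance inflated relative to the rest
  gp <- equal_group_params()
  gp[["later-male"]] <- ref_params(A_q = 0.4 * 3, C_q = 0.1 * 3,
                                   E_q = 0.5 * 3)
  pairs <- simulate_ccc_study(250, gp, seed = 46)
  suite <- run_comparison_suite(pairs, control = list(seed = 1))
  expect_s3_class(suite, "data.frame")
  omni <- suite[suite$type == "omnibus", ]
  expect_setequal(omni$test,
                  c("threshold_age60", "threshold_age65",
                    "mean_quantity_age60", "mean_quantity_age65",
                    "causal_path", "initiation_ACE",
                    "quantity_specific_ACE", "quantity_specific_variance",
                    "total_quantity_variance"))
  expect_true(all(is.na(omni$error)))
  expect_true(all(omni$delta_minus2LL >= 0))
  expect_true(all(omni$p_value >= 0 & omni$p_value <= 1))
  # the planted variance difference is detected and followed up pairwise
  tv <- omni[omni$test == "total_quantity_variance", ]
  expect_lt(tv$p_value, 0.05)
  followups <- suite[suite$type == "pairwise" &
                       suite$test == "total_quantity_variance", ]
  expect_equal(nrow(followups), 4)
  expect_error(run_comparison_suite(
    pairs[pairs$group == "later-male", ]), "two groups")
})
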