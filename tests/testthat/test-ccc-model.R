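test_that("implied covariance matches hand algebra for MZ and DZ pairs", {
  p <- ref_params()
  S <- build_covariance(p, "MZ")
  # Var(Q) = b^2 + A_q + C_q + E_q = 0.36 + 1.0; cross-twin terms from
  # rA * A + C with rA = 1
  expect_equal(unname(diag(S)), c(1, 1.36, 1, 1.36))
  expect_equal(S["L1", "L2"], 0.7)
  expect_equal(S["Q1", "Q2"], 0.36 * 0.7 + 0.4 + 0.1)  # 0.752
  expect_equal(S["L1", "Q2"], 0.6 * 0.7)               # 0.42
  expect_equal(S, t(S))
  D <- build_covariance(p, "DZ")
  expect_equal(D["L1", "L2"], 0.5 * 0.5 + 0.2)         # 0.45
  expect_equal(D["Q1", "Q2"], 0.36 * 0.45 + 0.5 * 0.4 + 0.1)  # 0.462
})

test_that("implied covariance agrees with the empirical covariance of latent draws", {
  spec <- cohort_sim_spec("earlier",
                          n_pairs_per_zygosity = c(MZ = 0, DZ = 150000),
                          prop_female = 0,
                          group_params = list("earlier-male" = ref_params(),
                                              "earlier-female" = ref_params()))
  r <- simulate_twin_cohort(spec, seed = 8, keep_latent = TRUE)
  lat <- attr(r, "latent")
  # center quantities by their age-linked means before taking moments
  mu <- predict_mean_quantity(ref_params(), lat$age)
  emp <- cov(cbind(lat$L1, lat$Q1 - mu, lat$L2, lat$Q2 - mu))
  expect_equal(unname(emp), unname(build_covariance(ref_params(), "DZ")),
               tolerance = 0.02)
})

test_that("pair likelihood reproduces closed-form special cases", {
  p0 <- ccc_parameters(0, 0, 1, tau0 = 0)
  # independent liabilities, each below a zero threshold with P = 1/2
  expect_equal(pair_loglik(p0, make_obs(init1 = "no", init2 = "no")),
               log(0.25))
  # an impossibly low threshold makes a concordant-nonsmoking pair
  # an impossible observation
  plow <- ccc_parameters(0, 0, 1, tau0 = -39)
  expect_identical(pair_loglik(plow, make_obs()), -Inf)
  # non-initiator with a recorded quantity is a data error
  expect_error(pair_loglik(ref_params(),
                           make_obs(init1 = "no", init2 = "no", q1 = 3)),
               "quantity")
})

test_that("pair likelihood matches the quadrature oracle on all observation patterns", {
  set.seed(7)
  for (i in 1:12) {
    p <- random_ccc_params()
    zyg <- sample(c("MZ", "DZ"), 1)
    a1 <- runif(1, 55, 75)
    a2 <- runif(1, 55, 75)
    qdraw <- function(a) predict_mean_quantity(p, a) + rnorm(1, 0, 1.2)
    cases <- list(
      make_obs(zyg, a1, a2, "no", "no"),
      make_obs(zyg, a1, a2, "yes", "no", q1 = qdraw(a1)),
      make_obs(zyg, a1, a2, "no", "yes", q2 = qdraw(a2)),
      make_obs(zyg, a1, a2, "yes", "yes", q1 = qdraw(a1), q2 = qdraw(a2)),
      make_obs(zyg, a1, a2, "yes", "no"),
      make_obs(zyg, a1, a2, "yes", "yes"),
      make_obs(zyg, a1, a2, "yes", "yes", q1 = qdraw(a1)))
    for (obs in cases) {
      lik <- exp(pair_loglik(p, obs))
      oracle <- pair_lik_quad(p, zyg, a1, a2, obs$init1, obs$init2,
                              obs$q1, obs$q2)
      expect_equal(lik, oracle, tolerance = 1e-6,
                   label = sprintf("pattern (%s%s, %s%s), set %d",
                                   obs$init1,
                                   if (!is.na(obs$q1)) "+q" else "",
                                   obs$init2,
                                   if (!is.na(obs$q2)) "+q" else "", i))
    }
  }
})

test_that("singleton twins reduce to the univariate analogues", {
  p <- ref_params()
  t60 <- p$tau0
  expect_equal(pair_loglik(p, make_obs(init1 = "no", init2 = NA)),
               pnorm(t60, log.p = TRUE))
  expect_equal(pair_loglik(p, make_obs(init1 = NA, init2 = "yes")),
               pnorm(t60, lower.tail = FALSE, log.p = TRUE))
  # observed quantity: marginal density times conditional exceedance
  q <- 4.1
  Vq <- p$b^2 + p$A_q + p$C_q + p$E_q
  mcond <- p$b / Vq * (q - p$mu0)
  vcond <- 1 - p$b^2 / Vq
  expect_equal(pair_loglik(p, make_obs(init1 = "yes", q1 = q, init2 = NA)),
               dnorm(q, p$mu0, sqrt(Vq), log = TRUE) +
                 pnorm((t60 - mcond) / sqrt(vcond), lower.tail = FALSE,
                       log.p = TRUE))
  # both twins fully missing contribute nothing
  expect_equal(pair_loglik(p, make_obs(init1 = NA, init2 = NA)), 0)
})

test_that("initiation pattern probabilities sum to one with quantity integrated out", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_ccc_params()
    for (zyg in c("MZ", "DZ")) {
      a1 <- runif(1, 55, 75)
      a2 <- runif(1, 55, 75)
      tot <- sum(vapply(list(c("no", "no"), c("yes", "no"),
                             c("no", "yes"), c("yes", "yes")),
                        function(ii) exp(pair_loglik(p,
                          make_obs(zyg, a1, a2, ii[1], ii[2]))), 0))
      expect_equal(tot, 1, tolerance = 1e-6)
    }
  }
})

test_that("severed causal path factorizes into binary and quantity parts", {
  # with b = 0 and no quantity-specific A/C, quantities are independent
  # normals and the initiation block is a pure threshold model
  p <- ccc_parameters(0.5, 0.2, 0.3, b = 0, A_q = 0, C_q = 0, E_q = 0.8,
                      tau0 = 0.4, mu0 = 4.5)
  q1 <- 5.1
  q2 <- 3.9
  joint <- pair_loglik(p, make_obs("MZ", init1 = "yes", init2 = "yes",
                                   q1 = q1, q2 = q2))
  binary <- pair_loglik(p, make_obs("MZ", init1 = "yes", init2 = "yes"))
  expect_equal(joint,
               binary + dnorm(q1, 4.5, sqrt(0.8), log = TRUE) +
                 dnorm(q2, 4.5, sqrt(0.8), log = TRUE),
               tolerance = 1e-8)
  S <- build_covariance(p, "DZ")
  expect_true(all(S[c("L1", "L2"), c("Q1", "Q2")] == 0))
})

test_that("MZ cross-twin covariances dominate DZ when genetic components are nonnegative", {
  set.seed(13)
  for (i in 1:20) {
    p <- random_ccc_params()
    M <- build_covariance(p, "MZ")
    D <- build_covariance(p, "DZ")
    expect_true(M["L1", "L2"] >= D["L1", "L2"] - 1e-12)
    expect_true(M["Q1", "Q2"] >= D["Q1", "Q2"] - 1e-12)
  }
})

test_that("dataset deviance is additive and group-local", {
  pairs <- simulate_ccc_study(60, seed = 21)
  params <- equal_group_params()
  half1 <- pairs[seq_len(nrow(pairs)) %% 2 == 0, ]
  half2 <- pairs[seq_len(nrow(pairs)) %% 2 == 1, ]
  expect_equal(dataset_loglik(params, half1) + dataset_loglik(params, half2),
               dataset_loglik(params, pairs), tolerance = 1e-9)
  expect_equal(dataset_loglik(params, pairs[0, ]), 0)
  # perturbing one group's parameters moves only that group's contribution
  params2 <- params
  params2[["later-male"]] <- ref_params(b = 0.3)
  lm_rows <- pairs$group == "later-male"
  expect_equal(dataset_loglik(params2, pairs[!lm_rows, ]),
               dataset_loglik(params, pairs[!lm_rows, ]))
  expect_false(isTRUE(all.equal(dataset_loglik(params2, pairs[lm_rows, ]),
                                dataset_loglik(params, pairs[lm_rows, ]))))
  expect_error(dataset_loglik(params["earlier-male"], pairs), "group")
})

test_that("threshold and mean-quantity predictions are linear in age", {
  p <- ccc_parameters(0.5, 0.2, 0.3, tau0 = 1.0, tau_age = 0.02,
                      mu0 = 4, mu_age = -0.03, ref_age = 60)
  expect_equal(predict_threshold(p, 65), 1.1)
  expect_equal(predict_threshold(ccc_parameters(0.5, 0.2, 0.3, tau0 = 0.7),
                                 c(40, 60, 90)), rep(0.7, 3))
  expect_equal(predict_mean_quantity(p, 65), 4 - 0.15)
  expect_equal(predict_mean_quantity(p, 60), 4)
  # a higher threshold always implies a lower prevalence
  expect_true(all(diff(pnorm(-predict_threshold(p, 50:80))) < 0))
})

test_that("standardized decompositions are consistent ratios", {
  d <- standardize_components(ccc_parameters(0.5, 0.2, 0.3, b = 0,
                                             A_q = 0.4, C_q = 0,
                                             E_q = 0.6))
  expect_equal(d$h2_q, 0.4)
  expect_equal(d$e2_q, 0.6)
  expect_equal(d$shared_variance, 0)
  expect_equal(d$total_variance, d$specific_variance)
  d2 <- standardize_components(ccc_parameters(0.5, 0.2, 0.3, b = 0.5,
                                              A_q = 2, C_q = 1, E_q = 1))
  expect_equal(c(d2$h2_q, d2$c2_q, d2$e2_q), c(0.5, 0.25, 0.25))
  expect_equal(d2$h2_q + d2$c2_q + d2$e2_q, 1, tolerance = 1e-9)
  expect_equal(d2$h2 + d2$c2 + d2$e2, 1, tolerance = 1e-9)
  expect_equal(d2$total_variance, 0.25 + 4)
  set.seed(3)
  for (i in 1:10) {
    s <- standardize_components(random_ccc_params())
    expect_equal(s$h2_q + s$c2_q + s$e2_q, 1, tolerance = 1e-9)
    expect_equal(s$total_variance, s$shared_variance + s$specific_variance)
  }
})
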