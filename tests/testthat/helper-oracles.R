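# Shared fixtures and independent oracles for the test suite.

ccc_groups <- c("earlier-male", "earlier-female", "later-male",
                "later-female")

# Reference parameter set used across recovery experiments.
ref_params <- function(...) {
  args <- modifyList(list(A_init = 0.5, C_init = 0.2, E_init = 0.3,
                          b = 0.6, A_q = 0.4, C_q = 0.1, E_q = 0.5,
                          tau0 = 0.3, tau_age = 0.01,
                          mu0 = 5, mu_age = -0.02), list(...))
  do.call(ccc_parameters, args)
}

# All four study groups at the same generating values.
equal_group_params <- function(p = ref_params()) {
  setNames(rep(list(p), 4), ccc_groups)
}

# Independent bivariate-normal lower orthant by 1-D adaptive quadrature.
phi2_quad <- function(h, k, rho) {
  if (!is.finite(h) && h < 0) return(0)
  integrate(function(x) dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2)),
            -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Multivariate normal density without mvtnorm (kept deliberately simple).
dmvn <- function(x, mean, sigma) {
  d <- length(mean)
  e <- as.numeric(x - mean)
  q <- as.numeric(e %*% solve(sigma, e))
  exp(-0.5 * (d * log(2 * pi) + determinant(sigma)$modulus + q))
}

# Quadrature oracle for the likelihood of one observed pair pattern:
# integrates the joint latent normal density over the initiation region
# by nested adaptive 1-D quadrature, with observed quantities fixed at
# their values.  Independent of the package's conditional-decomposition
# implementation; only the implied covariance (tested separately against
# hand algebra) is shared.
pair_lik_quad <- function(params, zygosity, age1, age2, init1, init2,
                          q1 = NA, q2 = NA) {
  S <- build_covariance(params, zygosity)
  t1 <- predict_threshold(params, age1)
  t2 <- predict_threshold(params, age2)
  m1 <- predict_mean_quantity(params, age1)
  m2 <- predict_mean_quantity(params, age2)
  sel <- c("L1", if (!is.na(q1)) "Q1", "L2", if (!is.na(q2)) "Q2")
  Si <- S[sel, sel]
  mu <- c(0, if (!is.na(q1)) m1, 0, if (!is.na(q2)) m2)
  inv <- solve(Si)
  lcst <- -0.5 * (length(mu) * log(2 * pi) +
                    as.numeric(determinant(Si)$modulus))
  dens <- function(l1v, l2v) {
    x1 <- c(l1v, if (!is.na(q1)) q1)
    vapply(l2v, function(l2) {
      e <- c(x1, l2, if (!is.na(q2)) q2) - mu
      exp(lcst - 0.5 * sum(e * (inv %*% e)))
    }, 0)
  }
  lim <- function(init, t) if (init == "yes") c(t, t + 9) else c(t - 9, t)
  l1 <- lim(init1, t1)
  l2 <- lim(init2, t2)
  inner <- function(l1v) integrate(function(z) dens(l1v, z),
                                   l2[1], l2[2], rel.tol = 1e-10,
                                   abs.tol = 1e-13)$value
  integrate(Vectorize(inner), l1[1], l1[2], rel.tol = 1e-9,
            abs.tol = 1e-13)$value
}

# Draw a random valid CCC parameter set (for property-style suites).
random_ccc_params <- function() {
  A <- runif(1, 0, 0.7)
  C <- runif(1, 0, 0.9 - A)
  ccc_parameters(A_init = A, C_init = C, E_init = 1 - A - C,
                 b = runif(1, -0.9, 0.9),
                 A_q = runif(1, 0, 0.6), C_q = runif(1, 0, 0.4),
                 E_q = runif(1, 0.3, 1.2),
                 tau0 = runif(1, -1, 1), tau_age = runif(1, -0.03, 0.03),
                 mu0 = runif(1, -1, 6), mu_age = runif(1, -0.05, 0.05))
}

make_obs <- function(zygosity = "MZ", age1 = 60, age2 = 60,
                     init1 = "no", init2 = "no", q1 = NA, q2 = NA) {
  list(zygosity = zygosity, age1 = age1, age2 = age2,
       init1 = init1, init2 = init2, q1 = q1, q2 = q2)
}
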