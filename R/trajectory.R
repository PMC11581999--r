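#' Fixed effects and variance components of the quantity trajectory model
#'
#' Container for the three-level linear mixed model of cigarette quantity
#' across age: `quantity ~ intercept + cohort + sex + age + age^2 +
#' education + sex:cohort + age:cohort` with random intercepts for twin
#' pair and for individual, plus a residual.  Coefficient defaults are the
#' fitted fixed effects reported for the emulated study population (on the
#' 1-8 ordinal quantity scale, sex coded male = 0 / female = 1, cohort as
#' the numeric band index 1..7, age in years, education in years); variance
#' component defaults are calibrated so that the fixed effects explain
#' about 14% of the outcome variance under the default generator design
#' (see the methods vignette).
#'
#' @param beta_intercept,beta_cohort,beta_sex,beta_age,beta_age2,beta_education,beta_sex_cohort,beta_age_cohort
#'   Fixed-effect coefficients.
#' @param var_pair,var_individual,var_residual Nonnegative variance
#'   components of the pair intercept, individual intercept and residual.
#' @return A list of class `trajectory_parameters`.
#' @export
trajectory_parameters <- function(beta_intercept = 6.14,
                                  beta_cohort = -0.22,
                                  beta_sex = -1.67,
                                  beta_age = 0.05,
                                  beta_age2 = -7.6e-4,
                                  beta_education = -0.05,
                                  beta_sex_cohort = 0.09,
                                  beta_age_cohort = 1.8e-3,
                                  var_pair = 1.15,
                                  var_individual = 2.29,
                                  var_residual = 2.29) {
  if (any(c(var_pair, var_individual, var_residual) < 0))
    stop("variance components must be nonnegative")
  structure(list(beta_intercept = beta_intercept, beta_cohort = beta_cohort,
                 beta_sex = beta_sex, beta_age = beta_age,
                 beta_age2 = beta_age2, beta_education = beta_education,
                 beta_sex_cohort = beta_sex_cohort,
                 beta_age_cohort = beta_age_cohort,
                 var_pair = var_pair, var_individual = var_individual,
                 var_residual = var_residual),
            class = "trajectory_parameters")
}

traj_linpred <- function(p, cohort_index, sex, age, education) {
  p$beta_intercept + p$beta_cohort * cohort_index + p$beta_sex * sex +
    p$beta_age * age + p$beta_age2 * age^2 +
    p$beta_education * education +
    p$beta_sex_cohort * sex * cohort_index +
    p$beta_age_cohort * age * cohort_index
}

#' Simulate repeated measures of cigarette quantity
#'
#' Generates a longitudinal repeated-measures table under the three-level
#' model: individuals nested in twin pairs, up to four assessment waves,
#' outcome = fixed-effect linear predictor + pair intercept + individual
#' intercept + residual.  Pairs receive a birth year uniform over
#' `birth_year_range`; an individual contributes a row for every wave at
#' which their age falls inside `age_window` (mortality and attrition are
#' deliberately not modeled).
#'
#' @param n_pairs Number of twin pairs.
#' @param params A [trajectory_parameters()] object (generating values).
#' @param seed Integer seed.
#' @param birth_year_range Inclusive birth-year range.
#' @param assessment_years Assessment waves.
#' @param prop_female Probability a pair is female.
#' @param education_mean_sd Mean/SD of years of education (floor 4).
#' @param age_window Ages outside this window contribute no row.
#' @return Data frame with columns `pair_id, individual_id, cohort_index,
#'   sex, birth_year, age, education, quantity` — one row per individual
#'   per contributing assessment.
#' @export
simulate_longitudinal_quantity <- function(n_pairs, params =
                                             trajectory_parameters(),
                                           seed = 1,
                                           birth_year_range = c(1880, 1957),
                                           assessment_years =
                                             c(1975, 1981, 1990, 2011),
                                           prop_female = 0.55,
                                           education_mean_sd = c(10, 3),
                                           age_window = c(18, 95)) {
  if (any(c(params$var_pair, params$var_individual,
            params$var_residual) < 0))
    stop("variance components must be nonnegative")
  set.seed(as.integer(seed))
  by <- sample(birth_year_range[1]:birth_year_range[2], n_pairs,
               replace = TRUE)
  ci <- cohort_index_of(by)
  sex <- as.integer(runif(n_pairs) < prop_female)  # male 0 / female 1
  u_pair <- rnorm(n_pairs, 0, sqrt(params$var_pair))
  out <- vector("list", 2L)
  for (tw in 1:2) {
    edu <- pmax(4, round(rnorm(n_pairs, education_mean_sd[1],
                               education_mean_sd[2])))
    u_ind <- rnorm(n_pairs, 0, sqrt(params$var_individual))
    waves <- lapply(assessment_years, function(yr) {
      age <- yr - by
      keep <- age >= age_window[1] & age <= age_window[2]
      if (!any(keep)) return(NULL)
      idx <- which(keep)
      data.frame(pair_id = paste0("P", idx),
                 individual_id = paste0("P", idx, "_", tw),
                 cohort_index = ci[idx], sex = sex[idx],
                 birth_year = by[idx], age = age[idx], education = edu[idx],
                 mean = traj_linpred(params, ci[idx], sex[idx], age[idx],
                                     edu[idx]) + u_pair[idx] + u_ind[idx],
                 stringsAsFactors = FALSE)
    })
    out[[tw]] <- do.call(rbind, waves)
  }
  d <- do.call(rbind, out)
  d$quantity <- d$mean + rnorm(nrow(d), 0, sqrt(params$var_residual))
  d$mean <- NULL
  d <- d[order(d$pair_id, d$individual_id, d$age), ]
  rownames(d) <- NULL
  d
}

traj_formula <- quantity ~ cohort_index + sex + age + I(age^2) +
  education + sex:cohort_index + age:cohort_index

traj_beta_names <- c("beta_intercept", "beta_cohort", "beta_sex",
                     "beta_age", "beta_age2", "beta_education",
                     "beta_sex_cohort", "beta_age_cohort")

#' Fit the three-level mixed model of quantity across age
#'
#' Maximum-likelihood fit (not REML, so likelihood-ratio comparisons remain
#' valid) of the quantity trajectory model with nested random intercepts
#' for twin pair and individual, via [lme4::lmer()].  The fixed-effect
#' structure is fixed to the eight-term design of the study: cohort index,
#' sex, linear and quadratic age, education, and the sex-by-cohort and
#' age-by-cohort interactions.
#'
#' @param data A repeated-measures data frame as produced by
#'   [simulate_longitudinal_quantity()] (columns `pair_id, individual_id,
#'   cohort_index, sex, age, education, quantity`).
#' @return A list of class `trajectory_fit` with elements `params` (a
#'   [trajectory_parameters()] holding estimates), `se`, `tstat` (normal
#'   reference), `r2_marginal`, `n_obs`, `flags` (character vector, e.g.
#'   singular fits or non-identified individual/residual split), and the
#'   underlying `lmer` fit as `model`.
#' @export
fit_lmm <- function(data) {
  req <- c("pair_id", "individual_id", "cohort_index", "sex", "age",
           "education", "quantity")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(data$pair_id)) < 2) stop("need at least 2 pairs")
  X <- model.matrix(traj_formula[-2], data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  flags <- character()
  single <- max(table(data$individual_id)) < 2
  if (single)
    flags <- c(flags, paste("single measure per individual:",
                            "var_individual and var_residual",
                            "not separately identified;",
                            "individual intercept dropped"))
  fm <- if (single) {
    # the individual intercept is confounded with the residual; absorb it
    lme4::lmer(quantity ~ cohort_index + sex + age + I(age^2) +
                 education + sex:cohort_index + age:cohort_index +
                 (1 | pair_id), data = data, REML = FALSE)
  } else {
    lme4::lmer(quantity ~ cohort_index + sex + age + I(age^2) +
                 education + sex:cohort_index + age:cohort_index +
                 (1 | pair_id) + (1 | individual_id),
               data = data, REML = FALSE)
  }
  if (lme4::isSingular(fm, tol = 1e-5))
    flags <- c(flags, "singular fit: a variance component is at 0")
  beta <- lme4::fixef(fm)
  se <- sqrt(diag(as.matrix(stats::vcov(fm))))
  vc <- as.data.frame(lme4::VarCorr(fm))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v[1] else 0
  }
  params <- trajectory_parameters(
    beta_intercept = beta[["(Intercept)"]],
    beta_cohort = beta[["cohort_index"]],
    beta_sex = beta[["sex"]],
    beta_age = beta[["age"]],
    beta_age2 = beta[["I(age^2)"]],
    beta_education = beta[["education"]],
    beta_sex_cohort = beta[["cohort_index:sex"]],
    beta_age_cohort = beta[["cohort_index:age"]],
    var_pair = getv("pair_id"),
    var_individual = getv("individual_id"),
    var_residual = getv("Residual"))
  names(se) <- traj_beta_names[match(names(beta), c("(Intercept)",
    "cohort_index", "sex", "age", "I(age^2)", "education",
    "cohort_index:sex", "cohort_index:age"))]
  se <- se[traj_beta_names]
  est <- unlist(params[traj_beta_names])
  fit <- structure(list(params = params, se = se,
                        tstat = est / se,
                        n_obs = nrow(data), flags = flags, model = fm),
                   class = "trajectory_fit")
  fit$r2_marginal <- marginal_r2(fit, data)
  fit
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Three-level mixed model of quantity (ML)\n")
  est <- unlist(x$params[traj_beta_names])
  tab <- data.frame(estimate = est, se = x$se, t = x$tstat)
  print(round(tab, 5))
  cat(sprintf("variance components: pair %.3f, individual %.3f, residual %.3f\n",
              x$params$var_pair, x$params$var_individual,
              x$params$var_residual))
  cat(sprintf("marginal R2 = %.3f on %d observations\n",
              x$r2_marginal, x$n_obs))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Marginal variance explained by the fixed effects
#'
#' Variance of the fixed-effect linear predictor divided by that variance
#' plus the pair, individual and residual variance components (the marginal
#' R-squared of a mixed model).
#'
#' @param fit A `trajectory_fit` or a [trajectory_parameters()] object.
#' @param data The data over which to evaluate the fixed predictor.
#' @return A fraction in `[0, 1]`.
#' @export
marginal_r2 <- function(fit, data) {
  p <- if (inherits(fit, "trajectory_fit")) fit$params else fit
  eta <- traj_linpred(p, data$cohort_index, data$sex, data$age,
                      data$education)
  vf <- stats::var(eta)
  vf / (vf + p$var_pair + p$var_individual + p$var_residual)
}

#' Predicted quantity trajectory over age
#'
#' Evaluates the fixed-effect quadratic-in-age prediction for one sex and
#' cohort band, and reports the vertex (peak) age
#' `-(beta_age + beta_age_cohort * cohort_index) / (2 * beta_age2)` where
#' the age slope changes sign.  With a negative quadratic term the peak is
#' a maximum; otherwise it is undefined and flagged.
#'
#' @param params A [trajectory_parameters()] object.
#' @param sex Sex code (male 0 / female 1).
#' @param cohort_index Numeric cohort band index (1..7).
#' @param ages Age grid (years).
#' @param education Years of education held fixed (default 10).
#' @return List with `age`, `predicted`, `peak_age` (NA if undefined) and
#'   `peak_defined`.
#' @export
predict_trajectory <- function(params, sex, cohort_index, ages,
                               education = 10) {
  yhat <- traj_linpred(params, cohort_index, sex, ages, education)
  if (is.finite(params$beta_age2) && params$beta_age2 < 0) {
    peak <- -(params$beta_age + params$beta_age_cohort * cohort_index) /
      (2 * params$beta_age2)
    ok <- TRUE
  } else {
    peak <- NA_real_
    ok <- FALSE
  }
  list(age = ages, predicted = yhat, peak_age = peak, peak_defined = ok)
}
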