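#' Default CCC parameter sets for the four sex-by-cohort groups
#'
#' Calibration constants for the synthetic twin cohort, one
#' [ccc_parameters()] object per group label (`earlier-male`,
#' `earlier-female`, `later-male`, `later-female`).  The initiation ACE
#' decomposition (A = 0.5, C = 0.2, E = 0.3) is common to all groups, as is
#' the standardized quantity-specific decomposition (h2_q = 0.40, c2_q =
#' 0.02, e2_q = 0.58); groups differ in threshold level and age slope
#' (highest threshold and steepest age slope for later-cohort males), in
#' mean quantity (higher in males, higher in the earlier male cohort), in
#' the amount of quantity-specific variance (larger in males, largest for
#' later-cohort males) and in the causal path (attenuated in earlier-cohort
#' males).  See the methods vignette for the rationale behind each constant.
#'
#' @return Named list of four [ccc_parameters()] objects.
#' @export
default_group_params <- function() {
  dec <- c(A = 0.40, C = 0.02, E = 0.58)  # quantity-specific proportions
  mk <- function(tau0, tau_age, mu0, mu_age, s, b)
    ccc_parameters(A_init = 0.5, C_init = 0.2, E_init = 0.3, b = b,
                   A_q = dec["A"] * s, C_q = dec["C"] * s,
                   E_q = dec["E"] * s,
                   tau0 = tau0, tau_age = tau_age,
                   mu0 = mu0, mu_age = mu_age, ref_age = 60)
  list(
    "earlier-male"   = mk(0.30, 0.010, 5.6, -0.020, s = 1.2, b = 0.30),
    "earlier-female" = mk(0.35, 0.010, 4.6, -0.020, s = 0.8, b = 0.60),
    "later-male"     = mk(0.65, 0.030, 5.2, -0.015, s = 1.5, b = 0.60),
    "later-female"   = mk(0.32, 0.012, 4.4, -0.015, s = 0.8, b = 0.60))
}

#' Simulation specification for one synthetic twin supergroup
#'
#' Describes one analysis supergroup of the emulated twin study: same-sex
#' MZ and DZ pairs born in a band of years and assessed once at the
#' supergroup's defining wave (1975 for the "earlier" cohort born
#' 1901-1920, 2011 for the "later" cohort born 1945-1957).  Defaults follow
#' the descriptive calibration of the study population: the earlier cohort
#' is 60% female with age 62.9 (SD 5.3) on 55-75; the later cohort is 51%
#' female with age 60.3 (SD 3.8) on 53-67.
#'
#' @param supergroup `"earlier"` or `"later"`.
#' @param n_pairs_per_zygosity Scalar or named vector `c(MZ = , DZ = )`;
#'   the default MZ:DZ ratio is 1:2.
#' @param prop_female Probability that a pair is female.
#' @param assessment_year Defining assessment wave.
#' @param age_truncation Inclusive age range at assessment.
#' @param age_mean_sd Mean and SD of the (truncated-normal) age
#'   distribution at assessment.
#' @param group_params Named list of [ccc_parameters()]; must contain
#'   `<supergroup>-male` and `<supergroup>-female`.
#' @param education_mean_sd Mean and SD of years of education (truncated
#'   normal, floor 4).
#' @param ever_threshold_gap Distance below the regular-smoking threshold
#'   at which the ever-smoking threshold sits on the same liability.
#' @param quantity_cuts Cut points discretizing the latent quantity into
#'   the 8 ordinal categories of the daily-quantity item.
#' @param item_missing_rate Probability that an individual's smoking items
#'   are missing at the assessment.
#' @return A list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(supergroup = c("earlier", "later"),
                            n_pairs_per_zygosity = c(MZ = 1000, DZ = 2000),
                            prop_female = NULL,
                            assessment_year = NULL,
                            age_truncation = NULL,
                            age_mean_sd = NULL,
                            group_params = default_group_params(),
                            education_mean_sd = c(10, 3),
                            ever_threshold_gap = 0.6,
                            quantity_cuts = seq(1.5, 7.5, by = 1),
                            item_missing_rate = 0) {
  supergroup <- match.arg(supergroup)
  def <- if (supergroup == "earlier") {
    list(prop_female = 0.60, assessment_year = 1975,
         age_truncation = c(55, 75), age_mean_sd = c(62.9, 5.3))
  } else {
    list(prop_female = 0.51, assessment_year = 2011,
         age_truncation = c(53, 67), age_mean_sd = c(60.3, 3.8))
  }
  spec <- list(supergroup = supergroup,
               n_pairs_per_zygosity = n_pairs_per_zygosity,
               prop_female = prop_female %||% def$prop_female,
               assessment_year = assessment_year %||% def$assessment_year,
               age_truncation = age_truncation %||% def$age_truncation,
               age_mean_sd = age_mean_sd %||% def$age_mean_sd,
               group_params = group_params,
               education_mean_sd = education_mean_sd,
               ever_threshold_gap = ever_threshold_gap,
               quantity_cuts = quantity_cuts,
               item_missing_rate = item_missing_rate)
  validate_sim_spec(spec)
  structure(spec, class = "cohort_sim_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sim_spec <- function(spec) {
  n <- spec$n_pairs_per_zygosity
  if (length(n) == 1 && is.null(names(n))) n <- c(MZ = n, DZ = n)
  if (any(n < 0)) stop("n_pairs_per_zygosity must be >= 0")
  if (spec$prop_female < 0 || spec$prop_female > 1)
    stop("prop_female must lie in [0, 1]")
  if (spec$age_truncation[1] >= spec$age_truncation[2])
    stop("age_truncation must be an increasing pair")
  for (sx in c("male", "female")) {
    lab <- paste0(spec$supergroup, "-", sx)
    if (!lab %in% names(spec$group_params))
      stop("group_params has no entry for group '", lab, "'")
    p <- spec$group_params[[lab]]
    if (any(c(p$A_init, p$C_init, p$E_init, p$A_q, p$C_q, p$E_q) < 0))
      stop("generator variance components must be nonnegative (group '",
           lab, "')")
  }
  invisible(spec)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# Correlated ACE deviates for n pairs: additive-genetic cross-twin
# correlation rA, shared environment correlated 1, unique independent.
r_ace_pair <- function(n, A, C, E, rA) {
  a1 <- rnorm(n)
  a2 <- rA * a1 + sqrt(1 - rA^2) * rnorm(n)
  cc <- rnorm(n)
  cbind(sqrt(A) * a1 + sqrt(C) * cc + sqrt(E) * rnorm(n),
        sqrt(A) * a2 + sqrt(C) * cc + sqrt(E) * rnorm(n))
}

#' Simulate a synthetic twin-cohort roster
#'
#' Draws same-sex MZ and DZ twin pairs under the CCC generative model and
#' returns a roster in the long per-individual-per-assessment layout: the
#' initiation liability is an ACE-structured standard normal with an
#' age-linked threshold; an individual initiates regular smoking iff their
#' liability exceeds the group threshold at their age; initiators receive a
#' latent continuous quantity `b * L` plus quantity-specific ACE deviates
#' and an age-linked mean, discretized onto the 8-category daily-quantity
#' scale for the roster output.  Non-initiators have the quantity item
#' missing.  The ever-smoking item is generated from the same liability
#' with a lower threshold, so the roster supports never / ever-only /
#' regular descriptives.
#'
#' @param spec A [cohort_sim_spec()].
#' @param seed Integer seed; the roster is deterministic given `(spec, seed)`.
#' @param keep_latent If `TRUE`, attach the latent draws and an
#'   analysis-ready [pair_observations()] table (continuous quantity scores)
#'   as attributes `"latent"` and `"pairs"`.
#' @return A data frame with columns `individual_id, pair_id, zygosity,
#'   sex, birth_year, education, assess_year, age, ever_item, regular_item,
#'   quantity_category`; zero rows when `n_pairs_per_zygosity` is 0.
#' @export
simulate_twin_cohort <- function(spec, seed = 1, keep_latent = FALSE) {
  validate_sim_spec(spec)
  set.seed(as.integer(seed))
  n <- spec$n_pairs_per_zygosity
  if (length(n) == 1 && is.null(names(n))) n <- c(MZ = n, DZ = n)
  rows <- list()
  lat <- list()
  prs <- list()
  next_pair <- 1L
  for (z in c("MZ", "DZ")) {
    np <- as.integer(n[[z]])
    if (np <= 0) next
    sex <- ifelse(runif(np) < spec$prop_female, "female", "male")
    age <- round(rnorm_trunc(np, spec$age_mean_sd[1], spec$age_mean_sd[2],
                             spec$age_truncation[1] - 0.5,
                             spec$age_truncation[2] + 0.5))
    age <- pmin(pmax(age, spec$age_truncation[1]), spec$age_truncation[2])
    # the study population is born 1880-1957; clamp and recompute age
    birth_year <- pmin(pmax(spec$assessment_year - age, 1880L), 1957L)
    age <- spec$assessment_year - birth_year
    edu1 <- pmax(4, round(rnorm(np, spec$education_mean_sd[1],
                                spec$education_mean_sd[2])))
    edu2 <- pmax(4, round(rnorm(np, spec$education_mean_sd[1],
                                spec$education_mean_sd[2])))
    rA <- if (z == "MZ") 1 else 0.5
    L <- matrix(NA_real_, np, 2)
    Q <- matrix(NA_real_, np, 2)
    grp <- paste0(spec$supergroup, "-", sex)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      p <- spec$group_params[[g]]
      L[idx, ] <- r_ace_pair(length(idx), p$A_init, p$C_init, p$E_init, rA)
      dev <- r_ace_pair(length(idx), p$A_q, p$C_q, p$E_q, rA)
      mu <- p$mu0 + p$mu_age * (age[idx] - p$ref_age)
      Q[idx, ] <- mu + p$b * L[idx, ] + dev
    }
    thr <- matrix(NA_real_, np, 2)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      p <- spec$group_params[[g]]
      thr[idx, ] <- p$tau0 + p$tau_age * (age[idx] - p$ref_age)
    }
    init <- L >= thr
    ever <- L >= (thr - spec$ever_threshold_gap)
    qcat <- matrix(NA_integer_, np, 2)
    qcat[] <- pmin(pmax(findInterval(Q, spec$quantity_cuts) + 1L, 1L), 8L)
    qcat[!init] <- NA_integer_
    pid <- next_pair:(next_pair + np - 1L)
    next_pair <- next_pair + np
    miss <- matrix(runif(2 * np) < spec$item_missing_rate, np, 2)
    for (tw in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = paste0("P", pid, "_", tw),
        pair_id = paste0("P", pid),
        zygosity = z, sex = sex, birth_year = birth_year,
        education = if (tw == 1) edu1 else edu2,
        assess_year = spec$assessment_year, age = age,
        ever_item = ifelse(miss[, tw], NA,
                           ifelse(ever[, tw], "yes", "no")),
        regular_item = ifelse(miss[, tw], NA,
                              ifelse(init[, tw], "yes", "no")),
        quantity_category = ifelse(miss[, tw], NA_integer_, qcat[, tw]),
        stringsAsFactors = FALSE)
    }
    if (keep_latent) {
      lat[[z]] <- data.frame(pair_id = paste0("P", pid), zygosity = z,
                             group = grp, age = age,
                             L1 = L[, 1], L2 = L[, 2],
                             Q1 = Q[, 1], Q2 = Q[, 2])
      prs[[z]] <- data.frame(
        pair_id = paste0("P", pid), zygosity = z, group = grp,
        age1 = age, age2 = age,
        init1 = ifelse(miss[, 1], NA, ifelse(init[, 1], "yes", "no")),
        init2 = ifelse(miss[, 2], NA, ifelse(init[, 2], "yes", "no")),
        q1 = ifelse(init[, 1] & !miss[, 1], Q[, 1], NA_real_),
        q2 = ifelse(init[, 2] & !miss[, 2], Q[, 2], NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  roster <- if (length(rows)) do.call(rbind, rows) else empty_roster()
  roster <- roster[order(roster$pair_id, roster$individual_id), ]
  rownames(roster) <- NULL
  if (keep_latent) {
    attr(roster, "latent") <- do.call(rbind, lat)
    attr(roster, "pairs") <- pair_observations(do.call(rbind, prs))
  }
  roster
}

empty_roster <- function() {
  data.frame(individual_id = character(), pair_id = character(),
             zygosity = character(), sex = character(),
             birth_year = integer(), education = numeric(),
             assess_year = integer(), age = integer(),
             ever_item = character(), regular_item = character(),
             quantity_category = integer(), stringsAsFactors = FALSE)
}

#' Simulate analysis-ready CCC pair data for all four study groups
#'
#' Convenience wrapper for simulation experiments: draws `n_pairs_per_
#' zygosity` MZ and DZ pairs in each of the four sex-by-cohort groups under
#' the given parameters and returns a [pair_observations()] table with the
#' continuous latent quantity score of initiators (the score the CCC
#' likelihood consumes in simulation studies).
#'
#' @param n_pairs_per_zygosity Pairs per zygosity per group.
#' @param params_by_group Named list of [ccc_parameters()] for the four
#'   group labels; defaults to [default_group_params()].
#' @param seed Integer seed.
#' @return A [pair_observations()] data frame.
#' @export
simulate_ccc_study <- function(n_pairs_per_zygosity = 1000,
                               params_by_group = default_group_params(),
                               seed = 1) {
  set.seed(as.integer(seed))
  out <- list()
  for (g in names(params_by_group)) {
    sg <- sub("-(male|female)$", "", g)
    spec <- cohort_sim_spec(sg)
    p <- params_by_group[[g]]
    for (z in c("MZ", "DZ")) {
      np <- n_pairs_per_zygosity
      age <- round(rnorm_trunc(np, spec$age_mean_sd[1], spec$age_mean_sd[2],
                               spec$age_truncation[1] - 0.5,
                               spec$age_truncation[2] + 0.5))
      rA <- if (z == "MZ") 1 else 0.5
      L <- r_ace_pair(np, p$A_init, p$C_init, p$E_init, rA)
      dev <- r_ace_pair(np, p$A_q, p$C_q, p$E_q, rA)
      mu <- p$mu0 + p$mu_age * (age - p$ref_age)
      Q <- mu + p$b * L + dev
      thr <- p$tau0 + p$tau_age * (age - p$ref_age)
      init <- L >= thr
      out[[paste(g, z)]] <- data.frame(
        pair_id = paste0(g, "-", z, "-", seq_len(np)),
        zygosity = z, group = g, age1 = age, age2 = age,
        init1 = ifelse(init[, 1], "yes", "no"),
        init2 = ifelse(init[, 2], "yes", "no"),
        q1 = ifelse(init[, 1], Q[, 1], NA_real_),
        q2 = ifelse(init[, 2], Q[, 2], NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  pair_observations(do.call(rbind, out))
}
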