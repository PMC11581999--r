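#' Analysis-ready twin-pair observations
#'
#' Validates (and classes) a data frame of one row per twin pair, the unit
#' of analysis of the CCC model.  Required columns:
#'
#' * `pair_id` — pair identifier;
#' * `zygosity` — `"MZ"` or `"DZ"`;
#' * `group` — group label (e.g. `"earlier-male"`);
#' * `age1`, `age2` — age at assessment per twin (years; `NA` allowed for a
#'   missing co-twin);
#' * `init1`, `init2` — initiation of regular smoking, `"yes"`, `"no"` or
#'   `NA` (missing);
#' * `q1`, `q2` — quantity score, observed only for initiators (`NA`
#'   otherwise).
#'
#' A quantity recorded for a twin whose initiation status is `"no"` or
#' missing is a data-consistency error: individuals who do not initiate
#' carry no information on progression.
#'
#' @param df A data frame with the columns above.
#' @return The same data frame with class `pair_observations`.
#' @export
pair_observations <- function(df) {
  req <- c("pair_id", "zygosity", "group", "age1", "age2",
           "init1", "init2", "q1", "q2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing pair-observation columns: ", paste(miss, collapse = ", "))
  if (!all(df$zygosity %in% c("MZ", "DZ")))
    stop("zygosity must be 'MZ' or 'DZ'")
  bad1 <- !is.na(df$q1) & (is.na(df$init1) | df$init1 != "yes")
  bad2 <- !is.na(df$q2) & (is.na(df$init2) | df$init2 != "yes")
  if (any(bad1 | bad2))
    stop("quantity present for a twin without initiation = 'yes' in pair(s): ",
         paste(utils::head(df$pair_id[bad1 | bad2], 5), collapse = ", "))
  class(df) <- c("pair_observations", "data.frame")
  df
}

# Observation pattern codes shared with the C++ kernel; singleton patterns
# always live in the twin-1 slots (values swapped during preparation).
# A pair with both initiation statuses missing encodes NA and is dropped.
pattern_code <- function(init1, init2, q1obs, q2obs) {
  n <- length(init1)
  out <- rep(NA_integer_, n)
  na1 <- is.na(init1)
  na2 <- is.na(init2)
  both <- !na1 & !na2
  y1 <- init1 == "yes"
  y2 <- init2 == "yes"
  i <- both & !y1 & !y2
  out[i] <- 0L
  i <- both & y1 & !y2
  out[i] <- ifelse(q1obs[i], 1L, 4L)
  i <- both & !y1 & y2
  out[i] <- ifelse(q2obs[i], 2L, 5L)
  i <- both & y1 & y2
  out[i] <- ifelse(q1obs[i] & q2obs[i], 3L,
                   ifelse(q1obs[i], 7L, ifelse(q2obs[i], 8L, 6L)))
  one <- xor(na1, na2)  # marginalize the missing twin
  oy <- ifelse(na1, y2, y1)[one]
  oq <- ifelse(na1, q2obs, q1obs)[one]
  out[one] <- ifelse(!oy, 9L, ifelse(oq, 10L, 11L))
  out
}

# Precompute pattern codes and aligned vectors per group x zygosity so that
# repeated likelihood evaluations during optimization are pure vector math.
ccc_prepare <- function(pairs) {
  pairs <- pair_observations(as.data.frame(pairs))
  out <- list()
  for (g in unique(pairs$group)) {
    for (z in c("MZ", "DZ")) {
      d <- pairs[pairs$group == g & pairs$zygosity == z, , drop = FALSE]
      if (!nrow(d)) next
      pat <- pattern_code(d$init1, d$init2, !is.na(d$q1), !is.na(d$q2))
      keep <- !is.na(pat)
      d <- d[keep, , drop = FALSE]
      pat <- pat[keep]
      if (!nrow(d)) next
      # singleton patterns: fold the observed twin into slot 1
      swap <- pat %in% c(9L, 10L, 11L) & is.na(d$init1)
      a1 <- ifelse(swap, d$age2, d$age1)
      a2 <- ifelse(swap, d$age1, d$age2)
      q1 <- ifelse(swap, d$q2, d$q1)
      q2 <- ifelse(swap, d$q1, d$q2)
      blk <- list(pattern = as.integer(pat),
                  age1 = as.numeric(a1), age2 = as.numeric(a2),
                  q1 = ifelse(is.na(q1), 0, as.numeric(q1)),
                  q2 = ifelse(is.na(q2), 0, as.numeric(q2)),
                  weight = rep(1, length(pat)), n = nrow(d))
      out[[g]][[z]] <- aggregate_block(blk)
    }
  }
  structure(out, class = "ccc_data")
}

# Quantity-free patterns with identical (pattern, age1, age2) contribute
# identical log-likelihood terms; collapse them into weighted rows so that
# optimization cost scales with the number of distinct configurations, not
# the number of concordant-nonsmoking pairs.
aggregate_block <- function(blk) {
  dedup <- blk$pattern %in% c(0L, 4L, 5L, 6L, 9L, 11L)
  if (!any(dedup)) return(blk)
  key <- paste(blk$pattern[dedup], blk$age1[dedup], blk$age2[dedup])
  w <- table(key)
  first <- !duplicated(key)
  keep <- which(dedup)[first]
  wkeep <- as.numeric(w[key[first]])
  sel <- c(which(!dedup), keep)
  list(pattern = blk$pattern[sel], age1 = blk$age1[sel],
       age2 = blk$age2[sel], q1 = blk$q1[sel], q2 = blk$q2[sel],
       weight = c(rep(1, sum(!dedup)), wkeep), n = blk$n)
}

ccc_loglik_block <- function(block, params, zygosity) {
  rA <- if (zygosity == "MZ") 1 else 0.5
  rLL <- rA * params$A_init + params$C_init
  t1 <- params$tau0 + params$tau_age * (block$age1 - params$ref_age)
  t2 <- params$tau0 + params$tau_age * (block$age2 - params$ref_age)
  mu1 <- params$mu0 + params$mu_age * (block$age1 - params$ref_age)
  mu2 <- params$mu0 + params$mu_age * (block$age2 - params$ref_age)
  ccc_pair_loglik_cpp(block$pattern, t1, t2, block$q1, block$q2, mu1, mu2,
                      rLL, params$b, params$A_q, params$C_q, params$E_q, rA,
                      block$weight %||% numeric())
}

#' Log-likelihood contribution of one twin pair
#'
#' Exact full-information contribution of a single pair under the 4-variate
#' normal latent model, pattern by pattern: a concordant-nonsmoking pair
#' contributes a bivariate-normal orthant probability; an initiator with an
#' observed quantity contributes its marginal normal density times the
#' conditional orthant probability of the initiation statuses given the
#' quantity; initiators with missing quantity have the quantity integrated
#' out; a pair with one twin's initiation missing is reduced to the
#' univariate analogue for the observed twin.
#'
#' @param params A [ccc_parameters()] object.
#' @param obs A one-row data frame (or list) with fields `zygosity`, `age1`,
#'   `age2`, `init1`, `init2`, `q1`, `q2` as in [pair_observations()].
#' @return The log-likelihood contribution (`-Inf` for an impossible
#'   observation or a non-positive-definite implied covariance).
#' @examples
#' p <- ccc_parameters(0, 0, 1, tau0 = 0)
#' obs <- list(zygosity = "MZ", age1 = 60, age2 = 60,
#'             init1 = "no", init2 = "no", q1 = NA, q2 = NA)
#' pair_loglik(p, obs)  # log(0.25): independent liabilities, each P = 1/2
#' @export
pair_loglik <- function(params, obs) {
  obs <- as.list(obs)
  q1obs <- !is.null(obs$q1) && !is.na(obs$q1)
  q2obs <- !is.null(obs$q2) && !is.na(obs$q2)
  bad1 <- q1obs && (is.na(obs$init1) || obs$init1 != "yes")
  bad2 <- q2obs && (is.na(obs$init2) || obs$init2 != "yes")
  if (bad1 || bad2)
    stop("quantity present for a twin without initiation = 'yes'")
  pat <- pattern_code(obs$init1, obs$init2, q1obs, q2obs)
  if (is.na(pat)) return(0)  # fully missing pair carries no information
  swap <- pat %in% c(9L, 10L, 11L) && is.na(obs$init1)
  block <- list(pattern = pat,
                age1 = as.numeric(if (swap) obs$age2 else obs$age1),
                age2 = as.numeric(if (swap) obs$age1 else obs$age2),
                q1 = if (swap) (if (q2obs) obs$q2 else 0)
                     else (if (q1obs) obs$q1 else 0),
                q2 = if (swap) (if (q1obs) obs$q1 else 0)
                     else (if (q2obs) obs$q2 else 0))
  as.numeric(ccc_loglik_block(block, params, obs$zygosity))
}

#' Deviance (-2 log-likelihood) of a multigroup CCC dataset
#'
#' Sums pair-wise full-information log-likelihood contributions over all
#' pairs and returns minus twice the total, the quantity minimized by
#' [fit_multigroup()] and differenced by likelihood-ratio tests.
#'
#' @param params_by_group Named list of [ccc_parameters()], one per group
#'   label appearing in `pairs`.
#' @param pairs A [pair_observations()] data frame (or a prepared
#'   `ccc_data` object).
#' @return `-2 * sum(log-likelihood)`; `Inf` if any contribution is
#'   `-Inf` (e.g. a non-positive-definite implied covariance).
#' @export
dataset_loglik <- function(params_by_group, pairs) {
  data <- if (inherits(pairs, "ccc_data")) pairs else ccc_prepare(pairs)
  tot <- 0
  for (g in names(data)) {
    if (!g %in% names(params_by_group))
      stop("no parameters supplied for group '", g, "'")
    for (z in names(data[[g]])) {
      ll <- ccc_loglik_block(data[[g]][[z]], params_by_group[[g]], z)
      tot <- tot + sum(ll)
    }
  }
  -2 * tot
}
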