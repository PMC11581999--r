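# Two interchangeable free-parameter scales map onto ccc_parameters:
#
# "components": A_init, C_init, b, A_q, C_q, lEq (log E_q), tau0, tau_age,
#   mu0, mu_age.  Natural for parameter recovery and profile CIs on the
#   variance components themselves.
#
# "levels": A_init, C_init, b, pA_q, pC_q, lsq (log specific variance) or
#   lVq (log total quantity variance), t60, t65, m60, m65.  Thresholds and
#   means at ages 60 and 65, the standardized quantity-specific proportions
#   and the variance amounts are themselves free parameters, so every
#   comparison in the likelihood-ratio ladder is a plain equality
#   constraint (parameter sharing) rather than a nonlinear restriction.
#
# Both carry 10 free parameters per group and the same maximized
# likelihood; E_init is always 1 - A_init - C_init (liability variance
# fixed at 1 for identification) and E_q > 0 is enforced via logs.

theta_names <- function(parameterization, quantity_scale = "specific") {
  if (parameterization == "components")
    c("A_init", "C_init", "b", "A_q", "C_q", "lEq",
      "tau0", "tau_age", "mu0", "mu_age")
  else
    c("A_init", "C_init", "b", "pA_q", "pC_q",
      if (quantity_scale == "specific") "lsq" else "lVq",
      "t60", "t65", "m60", "m65")
}

# theta must be ordered as theta_names(); positional access keeps this on
# the optimizer's hot path.
theta_to_params <- function(theta, parameterization, quantity_scale,
                            ref_age = 60) {
  if (parameterization == "components") {
    Eq <- exp(theta[[6L]])
    if (!is.finite(Eq) || Eq <= 0) return(NULL)
    p <- list(A_init = theta[[1L]], C_init = theta[[2L]],
              E_init = 1 - theta[[1L]] - theta[[2L]],
              b = theta[[3L]], A_q = theta[[4L]], C_q = theta[[5L]],
              E_q = Eq, tau0 = theta[[7L]], tau_age = theta[[8L]],
              mu0 = theta[[9L]], mu_age = theta[[10L]], ref_age = ref_age)
  } else {
    s <- if (quantity_scale == "specific") exp(theta[[6L]])
         else exp(theta[[6L]]) - theta[[3L]]^2
    pE <- 1 - theta[[4L]] - theta[[5L]]
    if (!is.finite(s) || s <= 0 || pE <= 0) return(NULL)
    p <- list(A_init = theta[[1L]], C_init = theta[[2L]],
              E_init = 1 - theta[[1L]] - theta[[2L]],
              b = theta[[3L]], A_q = theta[[4L]] * s,
              C_q = theta[[5L]] * s, E_q = pE * s,
              tau0 = theta[[7L]], tau_age = (theta[[8L]] - theta[[7L]]) / 5,
              mu0 = theta[[9L]], mu_age = (theta[[10L]] - theta[[9L]]) / 5,
              ref_age = ref_age)
  }
  class(p) <- "ccc_parameters"
  p
}

params_to_theta <- function(p, parameterization, quantity_scale) {
  if (parameterization == "components") {
    c(A_init = p$A_init, C_init = p$C_init, b = p$b,
      A_q = p$A_q, C_q = p$C_q, lEq = log(p$E_q),
      tau0 = p$tau0, tau_age = p$tau_age, mu0 = p$mu0, mu_age = p$mu_age)
  } else {
    s <- p$A_q + p$C_q + p$E_q
    c(A_init = p$A_init, C_init = p$C_init, b = p$b,
      pA_q = p$A_q / s, pC_q = p$C_q / s,
      if (quantity_scale == "specific") c(lsq = log(s))
      else c(lVq = log(p$b^2 + s)),
      t60 = p$tau0, t65 = p$tau0 + 5 * p$tau_age,
      m60 = p$mu0, m65 = p$mu0 + 5 * p$mu_age)
  }
}

#' Multigroup CCC model specification
#'
#' Declares the groups to model simultaneously, the free-parameter scale,
#' and any equality constraints across groups.  Each group carries 10 free
#' parameters; each constraint replaces the per-group copies of one
#' parameter by a single shared parameter.
#'
#' @param groups Character vector of group labels.
#' @param parameterization `"components"` (direct variance components) or
#'   `"levels"` (thresholds/means at ages 60 and 65, standardized
#'   quantity-specific proportions and a variance amount).
#' @param quantity_scale For `"levels"`: `"specific"` frees the log
#'   quantity-specific variance, `"total"` the log total quantity variance
#'   (specific plus causal-path share) — the scale on which total-variance
#'   equality across groups is a linear constraint.
#' @return A list of class `ccc_model_spec`.
#' @seealso [constrain()], [fit_multigroup()]
#' @export
ccc_model_spec <- function(groups = c("earlier-male", "earlier-female",
                                      "later-male", "later-female"),
                           parameterization = c("components", "levels"),
                           quantity_scale = c("specific", "total")) {
  parameterization <- match.arg(parameterization)
  quantity_scale <- match.arg(quantity_scale)
  structure(list(groups = groups, parameterization = parameterization,
                 quantity_scale = quantity_scale, constraints = list()),
            class = "ccc_model_spec")
}

#' Equate a parameter across groups
#'
#' Returns a specification in which the named free parameter is shared by
#' the given groups; the free-parameter count drops by `length(groups) - 1`.
#' Equating across a single group is a no-op.
#'
#' @param spec A [ccc_model_spec()].
#' @param parameter Free-parameter name on the spec's scale.
#' @param groups Groups to equate (default: all groups in the spec).
#' @return The modified spec.
#' @export
constrain <- function(spec, parameter, groups = spec$groups) {
  nm <- theta_names(spec$parameterization, spec$quantity_scale)
  if (!parameter %in% nm)
    stop("unknown parameter '", parameter, "' for the ",
         spec$parameterization, " parameterization")
  if (!all(groups %in% spec$groups))
    stop("unknown group(s): ",
         paste(setdiff(groups, spec$groups), collapse = ", "))
  groups <- unique(groups)
  if (length(groups) < 2) return(spec)
  for (ct in spec$constraints)
    if (ct$parameter == parameter && length(intersect(ct$groups, groups)))
      stop("parameter '", parameter, "' already constrained for ",
           "overlapping groups")
  spec$constraints <- c(spec$constraints,
                        list(list(parameter = parameter, groups = groups)))
  spec
}

# Map (group, parameter) -> index into the packed free-parameter vector.
build_param_map <- function(spec) {
  nm <- theta_names(spec$parameterization, spec$quantity_scale)
  map <- expand.grid(parameter = nm, group = spec$groups,
                     stringsAsFactors = FALSE)
  map$label <- paste0(map$group, "|", map$parameter)
  map$index <- NA_integer_
  nxt <- 0L
  for (ct in spec$constraints) {
    nxt <- nxt + 1L
    sel <- map$parameter == ct$parameter & map$group %in% ct$groups
    map$index[sel] <- nxt
    map$label[sel] <- paste0(ct$parameter, "[",
                             paste(ct$groups, collapse = "+"), "]")
  }
  free <- which(is.na(map$index))
  map$index[free] <- nxt + seq_along(free)
  map
}

n_free_params <- function(spec) max(build_param_map(spec)$index)

theta_labels <- function(map) {
  lab <- character(max(map$index))
  lab[map$index] <- map$label
  lab
}

unpack_theta <- function(theta, map, spec) {
  out <- list()
  for (g in spec$groups) {
    sel <- map$group == g
    th <- theta[map$index[sel]]
    names(th) <- map$parameter[sel]
    out[[g]] <- theta_to_params(th, spec$parameterization,
                                spec$quantity_scale)
  }
  out
}

flatten_blocks <- function(data_g) {
  zs <- names(data_g)
  len <- vapply(data_g, function(b) length(b$pattern), 0L)
  g <- function(f) unlist(lapply(data_g, `[[`, f), use.names = FALSE)
  list(pattern = as.integer(g("pattern")), age1 = g("age1"),
       age2 = g("age2"), q1 = g("q1"), q2 = g("q2"),
       weight = g("weight"),
       cfg = rep(seq_along(zs) - 1L, len),
       rA = ifelse(zs == "MZ", 1, 0.5))
}

# Deviance of one group as a function of its own 10-parameter vector; a
# single C++ call per evaluation over the group's flattened pair rows.
ccc_group_objective <- function(data_g, spec, par_names, penalty = 1e10) {
  fl <- flatten_blocks(data_g)
  dage1 <- fl$age1 - 60
  dage2 <- fl$age2 - 60
  K <- length(fl$rA)
  prm <- spec$parameterization
  qsc <- spec$quantity_scale
  function(th) {
    p <- theta_to_params(th, prm, qsc)
    if (is.null(p)) return(penalty)
    da1 <- dage1 + (60 - p$ref_age)
    da2 <- dage2 + (60 - p$ref_age)
    cfgmat <- vapply(fl$rA, function(r)
      c(r * p$A_init + p$C_init, p$b, p$A_q, p$C_q, p$E_q, r),
      numeric(6L))
    ll <- ccc_loglik_sum_cpp(fl$pattern,
                             p$tau0 + p$tau_age * da1,
                             p$tau0 + p$tau_age * da2,
                             fl$q1, fl$q2,
                             p$mu0 + p$mu_age * da1,
                             p$mu0 + p$mu_age * da2,
                             fl$weight, fl$cfg, cfgmat)
    if (!is.finite(ll)) return(penalty)
    -2 * ll
  }
}

ccc_objective <- function(data, spec, map, penalty = 1e10) {
  gobjs <- lapply(spec$groups, function(g)
    ccc_group_objective(data[[g]], spec,
                        map$parameter[map$group == g], penalty))
  gidx <- lapply(spec$groups, function(g) map$index[map$group == g])
  function(theta) {
    tot <- 0
    for (i in seq_along(gobjs)) {
      v <- gobjs[[i]](theta[gidx[[i]]])
      if (v >= penalty) return(penalty)
      tot <- tot + v
    }
    tot
  }
}

# Moment-based starting values per group.
default_start <- function(data, group, spec) {
  inits <- qs <- numeric()
  for (z in names(data[[group]])) {
    blk <- data[[group]][[z]]
    pat <- blk$pattern
    y1 <- pat %in% c(1L, 3L, 4L, 6L, 7L, 8L, 10L, 11L)
    n1 <- pat %in% c(0L, 2L, 5L, 9L)
    inits <- c(inits, rep(1, sum(y1)), rep(0, sum(n1)))
    y2 <- pat %in% c(2L, 3L, 5L, 6L, 7L, 8L)
    n2 <- pat %in% c(0L, 1L, 4L)
    inits <- c(inits, rep(1, sum(y2)), rep(0, sum(n2)))
    qs <- c(qs, blk$q1[pat %in% c(1L, 3L, 7L, 10L)],
            blk$q2[pat %in% c(2L, 3L, 8L)])
  }
  prev <- min(max(mean(inits), 0.02), 0.98)
  mq <- if (length(qs)) mean(qs) else 0
  vq <- if (length(qs) > 1) max(var(qs), 0.1) else 1
  t0 <- qnorm(1 - prev)
  p <- list(A_init = 0.4, C_init = 0.2, E_init = 0.4,
            b = 0.3 * sqrt(vq), A_q = 0.3 * vq, C_q = 0.1 * vq,
            E_q = 0.5 * vq, tau0 = t0, tau_age = 0, mu0 = mq,
            mu_age = 0, ref_age = 60)
  class(p) <- "ccc_parameters"
  params_to_theta(p, spec$parameterization, spec$quantity_scale)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  code
}

# Blend a group's start toward its moment-based default until the group
# deviance is finite (equality constraints can make mapped starts land in
# an invalid region, e.g. a shared total variance below a group's b^2);
# the last resort severs the causal path, which is valid on every scale.
valid_group_start <- function(gobj, cur, fb, own, b_pos) {
  if (gobj(cur) < 1e9) return(cur)
  cand <- cur
  for (lam in c(0.5, 0.25, 0.1, 0)) {
    cand <- cur
    cand[own] <- lam * cur[own] + (1 - lam) * fb[own]
    if (gobj(cand) < 1e9) return(cand)
  }
  cand[b_pos] <- 0
  cand
}

run_starts <- function(obj, start, n_starts, jitter_sd, seed, iter_max) {
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(max(1, n_starts))) {
      st <- if (s == 1) start else start + rnorm(length(start), 0, jitter_sd)
      res <- tryCatch(nlminb(st, obj, control = list(iter.max = iter_max,
                                                     eval.max = 4000)),
                      error = function(e) NULL)
      if (is.null(res) || !is.finite(res$objective)) next
      if (is.null(best) || res$objective < best$objective) best <- res
    }
  })
  best
}

num_gradient <- function(f, x, rel_h = 1e-6) {
  g <- numeric(length(x))
  f0 <- f(x)
  for (i in seq_along(x)) {
    h <- rel_h * max(abs(x[i]), 1)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

#' Fit a multigroup CCC model by full-information maximum likelihood
#'
#' Minimizes the dataset deviance over the free parameters of every group
#' simultaneously, with equality constraints implemented by parameter
#' sharing.  Groups with no cross-group constraints are fitted as
#' independent blocks.  Optimization uses `nlminb` on a transformed scale
#' (variance amounts log-transformed, variance components unconstrained per
#' the direct symmetric parameterization) with seeded multi-start (default
#' 5 jittered starts).  Wald standard errors come from the numerical
#' Hessian of the deviance at the optimum; the fit is flagged converged
#' when the optimizer reports success and the scaled gradient sup-norm is
#' at most 1e-4.
#'
#' @param pairs A [pair_observations()] data frame (or prepared `ccc_data`).
#' @param spec A [ccc_model_spec()].
#' @param starts Optional start vector on the packed free-parameter scale
#'   (e.g. a previous fit's `theta`); defaults to moment-based starts.
#' @param control List: `n_starts` (default 5), `jitter_sd` (0.25), `seed`
#'   (1), `iter_max` (500), `hessian` (TRUE; FALSE skips Wald standard
#'   errors, a character vector of group labels restricts them to those
#'   groups of an unconstrained fit).
#' @return A list of class `ccc_fit`: `estimates` (per-group
#'   [ccc_parameters()]), `theta`, `labels`, `minus2LL`, `n_free`,
#'   `convergence` (optimizer code), `converged`, `grad_norm`, `se`
#'   (Wald, on the free-parameter scale), `spec`, `n_pairs`, `seed`.
#' @export
fit_multigroup <- function(pairs, spec = ccc_model_spec(), starts = NULL,
                           control = list()) {
  ctl <- modifyList(list(n_starts = 5, jitter_sd = 0.25, seed = 1,
                         iter_max = 500, hessian = TRUE), control)
  data <- if (inherits(pairs, "ccc_data")) pairs else ccc_prepare(pairs)
  empty <- setdiff(spec$groups, names(data))
  if (length(empty))
    stop("no pairs for group(s): ", paste(empty, collapse = ", "))
  map <- build_param_map(spec)
  n_free <- max(map$index)
  obj <- ccc_objective(data, spec, map)

  shared_idx <- unique(map$index[duplicated(map$index) |
                                   duplicated(map$index, fromLast = TRUE)])
  separable <- length(shared_idx) == 0 && is.null(starts)
  theta <- numeric(n_free)
  block_objs <- NULL
  if (separable) {
    m2ll <- 0
    code <- 0
    block_objs <- list()
    for (g in spec$groups) {
      sel <- map$group == g
      st <- default_start(data, g, spec)
      gobj <- ccc_group_objective(data[[g]], spec, map$parameter[sel])
      best <- run_starts(gobj, st, ctl$n_starts, ctl$jitter_sd,
                         ctl$seed, ctl$iter_max)
      if (is.null(best))
        stop("all optimizer starts failed for group '", g, "'")
      theta[map$index[sel]] <- best$par
      m2ll <- m2ll + best$objective
      code <- max(code, best$convergence)
      block_objs[[g]] <- list(obj = gobj, idx = map$index[sel])
    }
  } else {
    if (is.null(starts)) {
      starts <- numeric(n_free)
      for (g in spec$groups) {
        sel <- map$group == g
        st <- default_start(data, g, spec)
        idx <- map$index[sel]
        starts[idx] <- ifelse(idx %in% shared_idx & starts[idx] != 0,
                              (starts[idx] + st) / 2, st)
      }
    }
    gobjs <- lapply(spec$groups, function(g)
      ccc_group_objective(data[[g]], spec, map$parameter[map$group == g]))
    gidx <- lapply(spec$groups, function(g) map$index[map$group == g])
    # A single shared parameter is solved by nested (profile) optimization:
    # the outer 1-D search over the shared value accounts for the inner
    # re-optimization of every affected group, so there is no
    # coordinate-descent zig-zag; groups untouched by the constraint are
    # fitted once and contribute a constant.  Specs with several shared
    # parameters fall back to a scaled joint quasi-Newton fit.
    fit_nested_1d <- function(st) {
      sidx <- shared_idx
      aff <- which(vapply(gidx, function(ix) sidx %in% ix, TRUE))
      theta <- st
      const <- 0
      for (gi in setdiff(seq_along(gobjs), aff)) {
        r <- nlminb(theta[gidx[[gi]]], gobjs[[gi]],
                    control = list(iter.max = ctl$iter_max,
                                   rel.tol = 1e-9))
        theta[gidx[[gi]]] <- r$par
        const <- const + r$objective
      }
      warmsol <- lapply(aff, function(gi) theta[gidx[[gi]]])
      fbs <- lapply(spec$groups[aff], function(g)
        default_start(data, g, spec))
      prof <- function(s) {
        tot <- 0
        for (j in seq_along(aff)) {
          gI <- gidx[[aff[j]]]
          pos <- which(gI == sidx)
          own <- setdiff(seq_along(gI), pos)
          thg <- warmsol[[j]]
          thg[pos] <- s
          thg <- valid_group_start(gobjs[[aff[j]]], thg, fbs[[j]], own,
                                   which(map$parameter[map$group ==
                                           spec$groups[aff[j]]] == "b"))
          f <- function(v) {
            thg[own] <- v
            gobjs[[aff[j]]](thg)
          }
          r <- nlminb(thg[own], f,
                      control = list(iter.max = 150, rel.tol = 1e-7))
          thg[own] <- r$par
          warmsol[[j]] <<- thg
          tot <- tot + r$objective
        }
        tot
      }
      s0 <- st[sidx]
      w <- max(0.5, abs(s0))
      for (try in 1:4) {
        o <- optimize(prof, c(s0 - w, s0 + w), tol = 1e-4)
        if (o$minimum > s0 - w + 0.02 * w &&
            o$minimum < s0 + w - 0.02 * w) break
        s0 <- o$minimum
        w <- 2 * w
      }
      val <- prof(o$minimum)  # refresh warm solutions at the optimum
      for (j in seq_along(aff)) theta[gidx[[aff[j]]]] <- warmsol[[j]]
      theta[sidx] <- o$minimum
      list(par = theta, objective = val + const, convergence = 0L)
    }
    fit_from <- function(st) {
      # repair group blocks whose mapped starts fall in an invalid region
      if (obj(st) >= 1e9) {
        for (gi in seq_along(gobjs)) {
          idx <- gidx[[gi]]
          own <- which(!(idx %in% shared_idx))
          st[idx] <- valid_group_start(
            gobjs[[gi]], st[idx],
            default_start(data, spec$groups[gi], spec), own,
            which(map$parameter[map$group == spec$groups[gi]] == "b"))
        }
      }
      if (length(shared_idx) == 1) return(fit_nested_1d(st))
      nlminb(st, obj, scale = 1 / pmax(abs(st), 0.1),
             control = list(iter.max = ctl$iter_max, rel.tol = 1e-8))
    }
    best <- NULL
    with_seed(ctl$seed, {
      for (s in seq_len(max(1, ctl$n_starts))) {
        st <- if (s == 1) starts
              else starts + rnorm(length(starts), 0, ctl$jitter_sd)
        res <- tryCatch(fit_from(st), error = function(e) NULL)
        if (is.null(res) || !is.finite(res$objective)) next
        if (is.null(best) || res$objective < best$objective) best <- res
      }
    })
    if (is.null(best)) stop("all optimizer starts failed")
    theta <- best$par
    m2ll <- best$objective
    code <- best$convergence
  }

  # gradient check and Wald SEs; block-wise for unconstrained fits so the
  # cost stays 10-dimensional per group
  se <- rep(NA_real_, n_free)
  if (separable) {
    grad <- numeric(n_free)
    for (g in names(block_objs)) {
      bl <- block_objs[[g]]
      grad[bl$idx] <- num_gradient(bl$obj, theta[bl$idx])
      if (isTRUE(ctl$hessian) ||
          (is.character(ctl$hessian) && g %in% ctl$hessian)) {
        H <- tryCatch(optimHess(theta[bl$idx], bl$obj),
                      error = function(e) NULL)
        V <- if (!is.null(H)) tryCatch(2 * solve(H),
                                       error = function(e) NULL)
        if (!is.null(V)) {
          dv <- diag(V)
          se[bl$idx[dv > 0]] <- sqrt(dv[dv > 0])
        }
      }
    }
  } else {
    grad <- num_gradient(obj, theta)
    if (isTRUE(ctl$hessian)) {
      H <- tryCatch(optimHess(theta, obj), error = function(e) NULL)
      V <- if (!is.null(H)) tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        dv <- diag(V)
        se[dv > 0] <- sqrt(dv[dv > 0])
      }
    }
  }
  grad_scaled <- max(abs(grad) * pmax(abs(theta), 1)) /
    max(abs(m2ll), 1)
  structure(list(estimates = unpack_theta(theta, map, spec),
                 theta = theta, labels = theta_labels(map), map = map,
                 minus2LL = m2ll, n_free = n_free,
                 convergence = code,
                 converged = code == 0 && grad_scaled <= 1e-4,
                 grad_norm = grad_scaled, se = setNames(se,
                                                       theta_labels(map)),
                 spec = spec,
                 n_pairs = vapply(data, function(g)
                   sum(vapply(g, `[[`, 0, "n")), 0)[spec$groups],
                 seed = ctl$seed, n_starts = ctl$n_starts),
            class = "ccc_fit")
}

#' @export
print.ccc_fit <- function(x, ...) {
  cat("Multigroup CCC fit (", x$spec$parameterization,
      " parameterization)\n", sep = "")
  cat(sprintf("  -2 lnL = %.3f with %d free parameters; %s\n",
              x$minus2LL, x$n_free,
              if (x$converged) "converged"
              else sprintf("NOT converged (code %d, scaled grad %.2g)",
                           x$convergence, x$grad_norm)))
  for (g in names(x$estimates)) {
    cat("group", g, sprintf("(%d pairs):\n", x$n_pairs[[g]]))
    print(x$estimates[[g]])
  }
  invisible(x)
}

#' Likelihood-ratio test between nested CCC fits
#'
#' Compares a restricted fit to the fit with the parameters freely
#' estimated: the difference in deviance is referred to a chi-square with
#' degrees of freedom equal to the difference in free-parameter counts.
#' Small negative differences (numerical noise up to 1e-6) are clamped to
#' zero; larger negative differences indicate an optimization failure and
#' raise an error.
#'
#' @param full,reduced `ccc_fit` objects, `reduced` nested in `full`.
#' @return Data frame row with `delta_minus2LL`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  df <- full$n_free - reduced$n_free
  if (df < 1) stop("reduced model is not a genuine restriction (df < 1)")
  if (!identical(sort(full$spec$groups), sort(reduced$spec$groups)))
    stop("fits do not model the same groups; not nested")
  delta <- reduced$minus2LL - full$minus2LL
  if (delta < -1e-6)
    stop("reduced fit beats full fit (delta = ", format(delta),
         "); optimization failure")
  delta <- max(delta, 0)
  data.frame(delta_minus2LL = delta, df = df,
             p_value = pchisq(delta, df, lower.tail = FALSE))
}

# Bisect a one-sided profile-deviance crossing.  pf must be increasing in
# |v - est| near the optimum; flags non-monotonicity / open bounds.
profile_side <- function(pf, est, bound, target, min_dev, tol, max_iter) {
  f_bound <- pf(bound)
  if (f_bound < target)
    return(list(value = NA_real_, flag = "open"))
  lo <- est
  hi <- bound
  flag <- "converged"
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- pf(mid)
    if (fm < min_dev - 1e-6) flag <- "unreliable"
    if (fm < target) lo <- mid else hi <- mid
    if (abs(hi - lo) < tol) break
  }
  list(value = (lo + hi) / 2, flag = flag)
}

#' Profile-likelihood confidence interval for one free parameter
#'
#' Bounds are the parameter values at which the profile deviance (deviance
#' re-minimized over all other free parameters) rises `qchisq(level, 1)`
#' above its minimum, located by bisection (tolerance 1e-3 on the parameter
#' scale, at most 60 iterations per side).  If the rise is not reached
#' inside the search box the bound is reported open (`NA` with flag
#' `"open"`); if the profile dips below the fitted minimum beyond numerical
#' tolerance the bound is flagged `"unreliable"`.
#'
#' @param pairs The pair data the fit was computed on.
#' @param spec The [ccc_model_spec()] used.
#' @param fit The converged [fit_multigroup()] result.
#' @param parameter Free-parameter label as in `fit$labels` (e.g.
#'   `"earlier-male|b"`).
#' @param level Confidence level (default 0.95).
#' @param box Half-width of the search box around the estimate; defaults
#'   to 6 Wald SEs (or 2 if the SE is unavailable).
#' @param tol,max_iter Bisection tolerance and per-side iteration cap.
#' @return List with `lower`, `upper`, `estimate`, `flags` (per side) and
#'   `method = "profile"`.
#' @export
profile_ci <- function(pairs, spec, fit, parameter, level = 0.95,
                       box = NULL, tol = 1e-3, max_iter = 60) {
  data <- if (inherits(pairs, "ccc_data")) pairs else ccc_prepare(pairs)
  idx <- match(parameter, fit$labels)
  if (is.na(idx)) stop("unknown parameter label: ", parameter)
  map <- fit$map
  est <- fit$theta[idx]
  se <- fit$se[[idx]]
  if (is.null(box))
    box <- if (is.finite(se) && !is.na(se)) 6 * se else 2
  crit <- qchisq(level, 1)
  target <- fit$minus2LL + crit

  # With no cross-group constraints only the parameter's own group responds
  # to the profiled value; the other groups' deviance is a constant carried
  # over from the fit.
  if (!length(spec$constraints) && grepl("|", parameter, fixed = TRUE)) {
    grp <- sub("\\|.*$", "", parameter)
    sel <- map$group == grp
    gobj <- ccc_group_objective(data[[grp]], spec, map$parameter[sel])
    gidx <- map$index[sel]
    const <- fit$minus2LL - gobj(fit$theta[gidx])
    obj_fun <- function(th_full) const + gobj(th_full[gidx])
    free_idx <- setdiff(gidx, idx)
  } else {
    obj_fun <- ccc_objective(data, spec, map)
    free_idx <- setdiff(seq_along(fit$theta), idx)
  }
  # warm-start each inner re-optimization from the solution at the nearest
  # previously profiled value (bisection revisits neighbourhoods)
  cache <- list(v = est, sol = list(fit$theta[free_idx]))
  base <- fit$theta
  pf <- function(v) {
    th <- base
    th[idx] <- v
    if (!length(free_idx)) return(obj_fun(th))
    st <- cache$sol[[which.min(abs(cache$v - v))]]
    inner <- function(fr) {
      th[free_idx] <- fr
      obj_fun(th)
    }
    res <- nlminb(st, inner,
                  control = list(iter.max = 150, rel.tol = 1e-6))
    cache$v <<- c(cache$v, v)
    cache$sol[[length(cache$sol) + 1L]] <<- res$par
    res$objective
  }
  lower <- profile_side(pf, est, est - box, target, fit$minus2LL, tol,
                        max_iter)
  upper <- profile_side(pf, est, est + box, target, fit$minus2LL, tol,
                        max_iter)
  list(lower = lower$value, upper = upper$value, estimate = est,
       flags = c(lower = lower$flag, upper = upper$flag),
       method = "profile", level = level)
}

#' Warm starting values for a constrained refit
#'
#' Maps a full (less constrained) fit's estimates onto the packed
#' free-parameter vector of a constrained spec, starting each shared
#' parameter at the mean of the group estimates it replaces.
#'
#' @param full_fit A [fit_multigroup()] result whose spec shares the
#'   parameterization of `spec`.
#' @param spec The constrained [ccc_model_spec()].
#' @return A numeric start vector for [fit_multigroup()].
#' @export
constrained_starts <- function(full_fit, spec) {
  if (full_fit$spec$parameterization != spec$parameterization ||
      full_fit$spec$quantity_scale != spec$quantity_scale)
    stop("parameterizations differ between full fit and constrained spec")
  mapc <- build_param_map(spec)
  st <- numeric(max(mapc$index))
  st[mapc$index] <- ave(full_fit$theta[full_fit$map$index], mapc$index)
  st
}

suite_tests <- list(
  list(name = "threshold_age60", parameters = "t60", scale = "specific"),
  list(name = "threshold_age65", parameters = "t65", scale = "specific"),
  list(name = "mean_quantity_age60", parameters = "m60",
       scale = "specific"),
  list(name = "mean_quantity_age65", parameters = "m65",
       scale = "specific"),
  list(name = "causal_path", parameters = "b", scale = "specific"),
  list(name = "initiation_ACE", parameters = c("A_init", "C_init"),
       scale = "specific"),
  list(name = "quantity_specific_ACE", parameters = c("pA_q", "pC_q"),
       scale = "specific"),
  list(name = "quantity_specific_variance", parameters = "lsq",
       scale = "specific"),
  list(name = "total_quantity_variance", parameters = "lVq",
       scale = "total"))

suite_pairwise <- function(groups) {
  sexes <- sub("^.*-", "", groups)
  cohorts <- sub("-[^-]*$", "", groups)
  cmb <- utils::combn(seq_along(groups), 2)
  keep <- apply(cmb, 2, function(ij)
    sexes[ij[1]] == sexes[ij[2]] || cohorts[ij[1]] == cohorts[ij[2]])
  lapply(which(keep), function(j) groups[cmb[, j]])
}

#' Run the omnibus-then-pairwise comparison ladder
#'
#' For each quantity of interest — predicted threshold at ages 60 and 65,
#' predicted mean quantity at 60 and 65, causal path, initiation ACE
#' decomposition, quantity-specific decomposition, amount of
#' quantity-specific variance, and total quantity variance — the suite
#' first tests the omnibus equality constraint across all groups; when the
#' omnibus test rejects at `alpha`, pairwise follow-ups (sex differences
#' within cohort and cohort differences within sex) locate the source.
#' Fit failures are recorded per row and do not abort the suite.
#'
#' @param pairs A [pair_observations()] data frame with at least two (for
#'   the standard ladder, four) sex-by-cohort groups.
#' @param alpha Follow-up trigger level (default 0.05).
#' @param control Passed to [fit_multigroup()]; constrained fits reuse the
#'   full fit's estimates as starts.
#' @return Data frame with one row per executed test: `test`, `type`
#'   (`"omnibus"` or `"pairwise"`), `groups`, `delta_minus2LL`, `df`,
#'   `p_value`, `error`.
#' @export
run_comparison_suite <- function(pairs, alpha = 0.05, control = list()) {
  data <- if (inherits(pairs, "ccc_data")) pairs else ccc_prepare(pairs)
  groups <- sort(names(data))
  if (length(groups) < 2)
    stop("the comparison suite needs at least two groups")
  ctl_full <- modifyList(list(n_starts = 3, hessian = FALSE), control)
  ctl_constrained <- modifyList(list(n_starts = 1, hessian = FALSE),
                                control)
  full <- list()
  for (sc in c("specific", "total")) {
    spec <- ccc_model_spec(groups, "levels", sc)
    full[[sc]] <- fit_multigroup(data, spec, control = ctl_full)
  }
  rows <- list()
  run_one <- function(test, grps, type) {
    spec <- ccc_model_spec(groups, "levels", test$scale)
    for (pm in test$parameters) spec <- constrain(spec, pm, grps)
    fl <- full[[test$scale]]
    res <- tryCatch({
      red <- fit_multigroup(data, spec,
                            starts = constrained_starts(fl, spec),
                            control = ctl_constrained)
      cmp <- lrt(fl, red)
      data.frame(test = test$name, type = type,
                 groups = paste(grps, collapse = "+"),
                 delta_minus2LL = cmp$delta_minus2LL, df = cmp$df,
                 p_value = cmp$p_value, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(test = test$name, type = type,
                 groups = paste(grps, collapse = "+"),
                 delta_minus2LL = NA_real_, df = NA_integer_,
                 p_value = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    res
  }
  for (test in suite_tests) {
    omni <- run_one(test, groups, "omnibus")
    rows[[length(rows) + 1L]] <- omni
    if (!is.na(omni$p_value) && omni$p_value < alpha &&
        length(groups) > 2) {
      for (pr in suite_pairwise(groups))
        rows[[length(rows) + 1L]] <- run_one(test, pr, "pairwise")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ccc_comparison_suite", "data.frame")
  out
}
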