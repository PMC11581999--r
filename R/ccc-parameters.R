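#' Parameters of the causal-contingent-common (CCC) twin model
#'
#' Bundles the parameters of the CCC ACE model for one sex-by-cohort group:
#' an ACE decomposition of the liability to initiate regular smoking
#' (standardized so that `A_init + C_init + E_init = 1`, the usual
#' liability-scale identification for binary data), a causal path `b`
#' carrying initiation liability into cigarette quantity, quantity-specific
#' ACE components on the quantity scale, and linear age moderation of the
#' initiation threshold and of the quantity mean.
#'
#' The direct symmetric parameterization is used throughout: variance
#' components are estimated directly and may individually be negative, which
#' keeps likelihood-ratio tests unbiased; only `E_q` is constrained positive
#' so the quantity distribution stays proper.
#'
#' @param A_init,C_init,E_init Liability variance components for initiation.
#'   If `E_init` is `NULL` it is set to `1 - A_init - C_init`; otherwise the
#'   three must sum to 1 (tolerance 1e-8).
#' @param b Causal path from initiation liability (SD units) to quantity.
#' @param A_q,C_q,E_q Quantity-specific variance components (quantity
#'   units squared); `E_q` must be strictly positive.
#' @param tau0 Initiation threshold at the reference age.
#' @param tau_age Threshold slope per year of age.
#' @param mu0 Quantity mean at the reference age.
#' @param mu_age Quantity mean slope per year of age.
#' @param ref_age Reference age in years (default 60).
#' @return An object of class `ccc_parameters`.
#' @examples
#' p <- ccc_parameters(A_init = 0.5, C_init = 0.2, b = 0.6,
#'                     A_q = 0.4, C_q = 0.1, E_q = 0.5,
#'                     tau0 = 0.3, mu0 = 5)
#' build_covariance(p, "MZ")
#' @export
ccc_parameters <- function(A_init, C_init, E_init = NULL, b = 0,
                           A_q = 0, C_q = 0, E_q = 1,
                           tau0 = 0, tau_age = 0,
                           mu0 = 0, mu_age = 0, ref_age = 60) {
  if (is.null(E_init)) E_init <- 1 - A_init - C_init
  if (abs(A_init + C_init + E_init - 1) > 1e-8)
    stop("initiation components must satisfy A_init + C_init + E_init = 1")
  if (!is.finite(E_q) || E_q <= 0)
    stop("E_q must be strictly positive")
  structure(list(A_init = A_init, C_init = C_init, E_init = E_init,
                 b = b, A_q = A_q, C_q = C_q, E_q = E_q,
                 tau0 = tau0, tau_age = tau_age,
                 mu0 = mu0, mu_age = mu_age, ref_age = ref_age),
            class = "ccc_parameters")
}

#' @export
print.ccc_parameters <- function(x, ...) {
  cat("CCC model parameters (ref age", x$ref_age, "years)\n")
  cat(sprintf("  initiation ACE: A=%.3f C=%.3f E=%.3f\n",
              x$A_init, x$C_init, x$E_init))
  cat(sprintf("  causal path b=%.3f; quantity ACE: A=%.3f C=%.3f E=%.3f\n",
              x$b, x$A_q, x$C_q, x$E_q))
  cat(sprintf("  threshold: %.3f %+.4f/yr; quantity mean: %.3f %+.4f/yr\n",
              x$tau0, x$tau_age, x$mu0, x$mu_age))
  invisible(x)
}

r_additive <- function(zygosity) {
  zygosity <- match.arg(as.character(zygosity), c("MZ", "DZ"))
  if (zygosity == "MZ") 1 else 0.5
}

#' Model-implied covariance of latent liabilities and quantities
#'
#' Returns the 4x4 covariance matrix of `(L1, Q1, L2, Q2)` implied by a set
#' of CCC parameters for a twin pair of the given zygosity.  Additive
#' genetic deviates correlate 1 across MZ co-twins and 0.5 across DZ
#' co-twins; shared-environment deviates correlate 1; unique-environment
#' deviates are independent.  The causal path `b` carries initiation
#' covariance into the quantity block.
#'
#' @param params A [ccc_parameters()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric 4x4 matrix with dimnames `L1, Q1, L2, Q2`.
#' @export
build_covariance <- function(params, zygosity) {
  rA <- r_additive(zygosity)
  VL <- params$A_init + params$C_init + params$E_init  # = 1 by construction
  b <- params$b
  Vq <- b^2 * VL + params$A_q + params$C_q + params$E_q
  cLL <- rA * params$A_init + params$C_init
  cQQ <- b^2 * cLL + rA * params$A_q + params$C_q
  cLQw <- b * VL
  cLQx <- b * cLL
  m <- matrix(c(VL,   cLQw, cLL,  cLQx,
                cLQw, Vq,   cLQx, cQQ,
                cLL,  cLQx, VL,   cLQw,
                cLQx, cQQ,  cLQw, Vq), 4, 4)
  dimnames(m) <- list(c("L1", "Q1", "L2", "Q2"), c("L1", "Q1", "L2", "Q2"))
  m
}

#' Predicted initiation threshold at a given age
#'
#' Evaluates the age-moderated threshold `tau0 + tau_age * (age - ref_age)`
#' on the standardized liability scale.  Predicted thresholds at ages 60 and
#' 65 are the quantities compared across sex-by-cohort groups.
#'
#' @param params A [ccc_parameters()] object.
#' @param age Age in years (vectorized).
#' @return Threshold(s) on the liability scale.
#' @export
predict_threshold <- function(params, age) {
  params$tau0 + params$tau_age * (age - params$ref_age)
}

#' Predicted mean quantity at a given age
#'
#' Evaluates `mu0 + mu_age * (age - ref_age)` on the quantity scale.
#'
#' @inheritParams predict_threshold
#' @return Mean quantity(ies) among initiators, before the causal-path and
#'   specific deviations.
#' @export
predict_mean_quantity <- function(params, age) {
  params$mu0 + params$mu_age * (age - params$ref_age)
}

#' Standardized variance decomposition of a CCC parameter set
#'
#' For initiation, the standardized components are the components themselves
#' (total liability variance is fixed at 1).  For quantity, the
#' quantity-specific components are standardized by the specific variance
#' `A_q + C_q + E_q`, and the variance shared with initiation is
#' `b^2 * Var(L)`; total quantity variance is the sum of the two.
#'
#' @param params A [ccc_parameters()] object.
#' @return A list with elements `h2, c2, e2` (initiation), `h2_q, c2_q,
#'   e2_q` (quantity-specific), `shared_variance`, `specific_variance` and
#'   `total_variance`.  If the specific variance is zero the standardized
#'   quantity triple is reported as `NA` (undefined), not as zeros.
#' @export
standardize_components <- function(params) {
  VL <- params$A_init + params$C_init + params$E_init
  spec_var <- params$A_q + params$C_q + params$E_q
  shared <- params$b^2 * VL
  if (spec_var <= 0) {
    trip <- c(NA_real_, NA_real_, NA_real_)
  } else {
    trip <- c(params$A_q, params$C_q, params$E_q) / spec_var
  }
  list(h2 = params$A_init / VL, c2 = params$C_init / VL,
       e2 = params$E_init / VL,
       h2_q = trip[1], c2_q = trip[2], e2_q = trip[3],
       shared_variance = shared, specific_variance = spec_var,
       total_variance = shared + spec_var)
}
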