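#' Transition probability function for EC movement
#'
#' Weight biasing the endothelial cell random walk,
#' `tau_hat(c, f) = ((alpha1 + c)/(alpha2 + c))^gamma1 *
#' ((beta1 + f)/(beta2 + f))^gamma2`.
#' The rational form approximates `c^gamma1 * f^(-gamma2)` over a wide range
#' while staying finite and positive at `c = 0` and `f = 0`: cells drift
#' toward high protease and low fibronectin without a singularity at the
#' rest state.
#'
#' @param c Protease concentration(s), >= 0. Vectorized.
#' @param f Fibronectin concentration(s), >= 0. Vectorized.
#' @param params A [model_params()] object.
#' @return `tau_hat`, strictly positive and finite.
#' @export
transition_probability <- function(c, f, params) {
  if (any(c < 0) || any(f < 0))
    stop("'c' and 'f' must be non-negative", call. = FALSE)
  ((params$alpha1 + c) / (params$alpha2 + c))^params$gamma1 *
    ((params$beta1 + f) / (params$beta2 + f))^params$gamma2
}

#' Logarithmic derivatives of the transition factors
#'
#' Returns `d log tau1 / dc = gamma1 (alpha2 - alpha1) /
#' ((alpha1 + c)(alpha2 + c))` and `d log tau2 / df = gamma2 (beta2 - beta1)
#' / ((beta1 + f)(beta2 + f))` -- the taxis coefficients of the expanded EC
#' equation. At the rest state these reduce to the lumped sensitivities:
#' the first component at `c = 0` is `rho1`, the second at `f = 1` is
#' `rho2` (see [compute_rho()]).
#'
#' @inheritParams transition_probability
#' @return A list with components `dlogtau1_dc` and `dlogtau2_df`
#'   (vectorized over `c` and `f` respectively).
#' @export
log_tau_derivatives <- function(c, f, params) {
  if (any(c < 0) || any(f < 0))
    stop("'c' and 'f' must be non-negative", call. = FALSE)
  list(
    dlogtau1_dc = params$gamma1 * (params$alpha2 - params$alpha1) /
      ((params$alpha1 + c) * (params$alpha2 + c)),
    dlogtau2_df = params$gamma2 * (params$beta2 - params$beta1) /
      ((params$beta1 + f) * (params$beta2 + f))
  )
}
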