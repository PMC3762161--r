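#' Fourier cosine spectrum of the substituted cell problem
#'
#' Shifting the cell perturbation by the particular solution `K theta(y)`
#' turns the linearized cell equation into a homogeneous Neumann heat
#' equation whose initial data is `-K theta(y)`; its cosine coefficients are
#' `C_0 = -2K * integral(theta) = -2K` and
#' `C_n = -2K * integral(theta(y) cos(n pi y) dy)`.
#' Coefficients are computed by adaptive quadrature. For the quartic bump
#' (`m = 2`) the closed form `C_n = 1440 K / (n^4 pi^4)` for even `n` and
#' `0` for odd `n` is available via [quartic_spectrum()] as a cross-check.
#'
#' @param theta An [initial_profile()] object.
#' @param K Lumped forcing constant.
#' @param N Truncation order (highest retained mode, >= 1).
#' @return An object of class `capform_spectrum`: list with `K`,
#'   `coefficients` (numeric vector `C_0 ... C_N`), `N`, `profile_label`,
#'   and `tail_bound`, an estimate of `sum_{n>N} |C_n|` assuming the
#'   `n^-4` decay of twice-differentiable profiles.
#' @export
fourier_spectrum <- function(theta, K, N = 200) {
  if (!inherits(theta, "capform_profile"))
    stop("'theta' must be an initial_profile object", call. = FALSE)
  if (N < 1) stop("'N' must be >= 1", call. = FALSE)
  coefs <- numeric(N + 1)
  coefs[1] <- -2 * K * stats::integrate(theta$fun, 0, 1, rel.tol = 1e-12,
                                        abs.tol = 1e-14)$value
  for (n in seq_len(N)) {
    ig <- stats::integrate(function(y) theta$fun(y) * cos(n * pi * y),
                           0, 1, rel.tol = 1e-12, abs.tol = 1e-14,
                           subdivisions = 400L)
    if (ig$message != "OK")
      stop(sprintf("quadrature failed for coefficient n = %d: %s",
                   n, ig$message), call. = FALSE)
    coefs[n + 1] <- -2 * K * ig$value
  }
  # n^-4 tail heuristic from the last retained magnitudes:
  # sum_{n>N} |C_N| (N/n)^4 ~ |C_N| N / 3
  c_last <- max(abs(coefs[seq(max(2, N - 3), N + 1)]))
  structure(list(K = K, coefficients = coefs, N = N,
                 profile_label = theta$label,
                 tail_bound = c_last * N / 3),
            class = "capform_spectrum")
}

#' Closed-form spectrum for the quartic bump profile
#'
#' For `theta(y) = 30 y^2 (1 - y)^2` the cosine coefficients are
#' `C_n = 1440 K / (n^4 pi^4)` for even `n >= 2`, zero for odd `n`, with
#' `C_0 = -2K`.
#'
#' @inheritParams fourier_spectrum
#' @return A `capform_spectrum` with exact coefficients (tail bound is the
#'   exact remainder sum).
#' @export
quartic_spectrum <- function(K, N = 200) {
  n <- seq_len(N)
  coefs <- c(-2 * K, ifelse(n %% 2 == 0, 1440 * K / (n^4 * pi^4), 0))
  tail_n <- seq(N + 1, N + 4000)
  tail <- sum(ifelse(tail_n %% 2 == 0,
                     abs(1440 * K) / (tail_n^4 * pi^4), 0))
  structure(list(K = K, coefficients = coefs, N = N,
                 profile_label = "bump-m2", tail_bound = tail),
            class = "capform_spectrum")
}

#' @export
print.capform_spectrum <- function(x, ...) {
  cat(sprintf("<capform_spectrum '%s'>  K=%g N=%d C0=%g tail<=%.3g\n",
              x$profile_label, x$K, x$N, x$coefficients[1], x$tail_bound))
  invisible(x)
}

#' Stability constant of the steady state
#'
#' The steady states of the linearized cell equation form the one-parameter
#' family `B + K theta(y)`. The long-time limit of the series solution fixes
#' `B = C_0 / 2 = -K` (for a unit-normalized profile) as the unique stable
#' choice: any other `B` is never approached by the evolution.
#'
#' @param spectrum A [fourier_spectrum()] object.
#' @return The constant `B = C_0 / 2`.
#' @export
stable_B <- function(spectrum) {
  if (!inherits(spectrum, "capform_spectrum"))
    stop("'spectrum' must be a capform_spectrum object", call. = FALSE)
  spectrum$coefficients[1] / 2
}

#' Steady-state cell perturbation profile
#'
#' Setting the time derivative to zero in the linearized cell equation
#' gives `n_ss(y) = B + K theta(y)` for an arbitrary constant `B`; see
#' [stable_B()] for the stable member.
#'
#' @param y Positions in `[0, 1]` (vectorized).
#' @param B Additive constant.
#' @param K Lumped forcing constant.
#' @param theta An [initial_profile()] object.
#' @return `n_ss(y)`.
#' @export
steady_state <- function(y, B, K, theta) {
  B + K * theta$fun(y)
}
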