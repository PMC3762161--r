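#' Closed-form first-order perturbation fields
#'
#' With initial data `v = epsilon theta(y)`, `c = 0`, `f = 1`, `eta = 1` and
#' the ansatz `v = epsilon w`, `c = epsilon xi`, `f = 1 - epsilon phi`,
#' `eta = 1 + epsilon n`, the linearized kinetics decouple:
#' the factor fraction `w` decays exponentially, the enzyme fraction `xi`
#' grows complementarily (`w + xi = theta` at all times), and the
#' fibronectin deficit `phi` relaxes through the logistic restoring rate
#' `beta` toward `mu theta / beta`.
#'
#' `solve_phi` switches to the confluent limit
#' `phi = mu theta [1/beta - e^(-beta t)/beta - t e^(-beta t)]` when
#' `|beta - lambda| / beta < 1e-6`, where the generic two-exponential form
#' loses significance.
#'
#' @param y Positions in `[0, 1]` (vectorized).
#' @param t Time, `t >= 0` (scalar).
#' @param theta An [initial_profile()] object.
#' @param lambda Factor consumption rate.
#' @param beta Fibronectin logistic rate.
#' @param mu Fibronectin degradation rate.
#' @return The requested first-order field evaluated at `(y, t)`.
#' @name perturbation_fields
NULL

#' @rdname perturbation_fields
#' @export
solve_w <- function(y, t, theta, lambda) {
  stopifnot(t >= 0)
  theta$fun(y) * exp(-lambda * t)
}

#' @rdname perturbation_fields
#' @export
solve_xi <- function(y, t, theta, lambda) {
  stopifnot(t >= 0)
  theta$fun(y) * (1 - exp(-lambda * t))
}

#' @rdname perturbation_fields
#' @export
solve_phi <- function(y, t, theta, lambda, beta, mu) {
  stopifnot(t >= 0)
  mu * theta$fun(y) * phi_bracket(t, lambda, beta)
}

# time factor of phi; confluent branch at beta ~ lambda
phi_bracket <- function(t, lambda, beta) {
  if (abs(beta - lambda) / beta < 1e-6) {
    1 / beta - exp(-beta * t) / beta - t * exp(-beta * t)
  } else {
    1 / beta - exp(-lambda * t) / (beta - lambda) +
      lambda * exp(-beta * t) / (beta * (beta - lambda))
  }
}

#' Series solution for the cell perturbation
#'
#' Evaluates the truncated Fourier cosine series
#' `n(y, t) = C_0/2 + sum_{n=1}^{N} C_n e^(-n^2 pi^2 D_eta t) cos(n pi y)
#' + K theta(y)`,
#' the solution of the large-time linearized cell equation with zero initial
#' perturbation and Neumann boundaries. The truncation error is bounded by
#' the spectrum's `tail_bound`, attached to the result as attribute
#' `"tail_bound"`.
#'
#' @param y Positions in `[0, 1]` (vectorized).
#' @param t Time, `t >= 0` (scalar).
#' @param spectrum A [fourier_spectrum()] built from the same profile and
#'   `K`; mismatched labels are an error.
#' @param theta The [initial_profile()] the spectrum was built from.
#' @param K Lumped forcing constant (must match the spectrum's).
#' @param D_eta EC diffusion coefficient.
#' @return `n(y, t)` as a numeric vector along `y`.
#' @export
series_n <- function(y, t, spectrum, theta, K, D_eta) {
  stopifnot(t >= 0)
  if (!inherits(spectrum, "capform_spectrum"))
    stop("'spectrum' must be a capform_spectrum object", call. = FALSE)
  if (!identical(spectrum$profile_label, theta$label))
    stop(sprintf("spectrum was built for profile '%s', not '%s'",
                 spectrum$profile_label, theta$label), call. = FALSE)
  if (abs(spectrum$K - K) > 1e-12 * max(1, abs(K)))
    stop("'K' does not match the spectrum's K", call. = FALSE)
  n_idx <- seq_len(spectrum$N)
  damp <- spectrum$coefficients[-1] * exp(-n_idx^2 * pi^2 * D_eta * t)
  # cos basis evaluated as an (y x n) matrix product
  series <- cos(outer(y, n_idx * pi)) %*% damp
  out <- spectrum$coefficients[1] / 2 + as.vector(series) + K * theta$fun(y)
  attr(out, "tail_bound") <- spectrum$tail_bound
  out
}

#' Assembled perturbation solutions of the full system
#'
#' Combines the first-order fields into the physical densities:
#' `v = epsilon theta e^(-lambda t)`, `c = epsilon theta (1 - e^(-lambda t))`,
#' `f = 1 - epsilon phi`, `eta = 1 + epsilon n`. The identity
#' `v + c = epsilon theta(y)` holds at every point and time. If `epsilon`
#' is large enough that `f` or `eta` becomes non-positive anywhere on the
#' requested points, a warning flags the breakdown of the perturbation
#' regime.
#'
#' @param y Positions in `[0, 1]` (vectorized).
#' @param t Time, `t >= 0` (scalar).
#' @param config A [perturbation_config()].
#' @param params A [model_params()] supplying `lambda`, `mu`, `beta`,
#'   `D_eta` (only those four are used on this route).
#' @param spectrum Optional precomputed [fourier_spectrum()]; built on the
#'   fly (order `N`) when absent.
#' @param N Truncation order used when `spectrum` is absent.
#' @return A list with numeric vectors `v`, `c`, `f`, `eta` along `y`.
#' @export
assemble_fields <- function(y, t, config, params, spectrum = NULL, N = 200) {
  stopifnot(t >= 0)
  if (is.null(spectrum))
    spectrum <- fourier_spectrum(config$theta, config$K, N)
  eps <- config$epsilon
  th <- config$theta
  v <- eps * solve_w(y, t, th, params$lambda)
  cc <- eps * solve_xi(y, t, th, params$lambda)
  f <- 1 - eps * solve_phi(y, t, th, params$lambda, params$beta, params$mu)
  eta <- 1 + eps * as.vector(series_n(y, t, spectrum, th, config$K,
                                      params$D_eta))
  if (any(f <= 0) || any(eta <= 0))
    warning("epsilon too large: f or eta non-positive; perturbation regime violated",
            call. = FALSE)
  list(v = v, c = cc, f = f, eta = eta)
}

#' Tabulate analytic fields on a space-time grid
#'
#' Evaluates [assemble_fields()] on a grid of positions and times and
#' returns a field-solution object shared with the numeric solvers.
#'
#' @param config A [perturbation_config()].
#' @param params A [model_params()].
#' @param grid A [make_grid()] object (or integer node count).
#' @param times Increasing vector of output times (>= 0).
#' @param N Series truncation order.
#' @return A `capform_fields` object: `y`, `times`, matrices `v`, `c`,
#'   `f`, `eta` (rows = times), `provenance = "analytic"`.
#' @export
analytic_fields <- function(config, params, grid = make_grid(101),
                            times = c(0, 0.05, 0.1), N = 200) {
  if (is.numeric(grid)) grid <- make_grid(grid)
  spectrum <- fourier_spectrum(config$theta, config$K, N)
  y <- grid$y
  nt <- length(times)
  m <- function() matrix(NA_real_, nt, length(y))
  v <- m(); cc <- m(); f <- m(); eta <- m()
  for (i in seq_len(nt)) {
    fl <- assemble_fields(y, times[i], config, params, spectrum = spectrum)
    v[i, ] <- fl$v; cc[i, ] <- fl$c; f[i, ] <- fl$f; eta[i, ] <- fl$eta
  }
  new_fields(grid, times, v, cc, f, eta, "analytic",
             params, config, extra = list(N = N,
                                          tail_bound = spectrum$tail_bound))
}
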