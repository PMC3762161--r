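#' Initial angiogenic-factor profile
#'
#' Wraps a unimodal disturbance profile `theta(y)` on `[0, 1]` together with
#' its first two derivatives. The profile must integrate to 1 (so that
#' `epsilon` alone sets the disturbance size), be non-negative, and have
#' vanishing endpoint derivatives `theta'(0) = theta'(1) = 0` -- the
#' condition under which the zero-flux boundary condition for the cell
#' perturbation reduces to a plain Neumann condition.
#'
#' @param fun Function of `y` returning `theta(y)`; vectorized.
#' @param deriv Function returning `theta'(y)`.
#' @param deriv2 Function returning `theta''(y)` (needed by the linearized
#'   transient solver).
#' @param label Short text label, used to match profiles to spectra.
#' @param check If `TRUE` (default), validate normalization (absolute
#'   quadrature tolerance 1e-10), non-negativity on a grid, and endpoint
#'   derivatives.
#' @return An object of class `capform_profile` with callable fields
#'   `fun`, `deriv`, `deriv2`.
#' @seealso [bump_profile()] for the `y^m (1-y)^m` family.
#' @export
initial_profile <- function(fun, deriv, deriv2 = NULL,
                            label = "custom", check = TRUE) {
  prof <- structure(list(fun = fun, deriv = deriv, deriv2 = deriv2,
                         label = label),
                    class = "capform_profile")
  if (check) {
    total <- stats::integrate(fun, 0, 1, rel.tol = 1e-12,
                              abs.tol = 1e-13)$value
    if (abs(total - 1) > 1e-10)
      stop(sprintf("profile '%s' integrates to %.12g, not 1", label, total),
           call. = FALSE)
    yg <- seq(0, 1, length.out = 201)
    if (any(fun(yg) < -1e-12))
      stop(sprintf("profile '%s' is negative on [0,1]", label),
           call. = FALSE)
    d0 <- deriv(0); d1 <- deriv(1)
    if (abs(d0) > 1e-10 || abs(d1) > 1e-10)
      warning(sprintf(paste0("profile '%s' has theta'(0)=%g, theta'(1)=%g; ",
                             "the zero-flux reduction to a plain Neumann ",
                             "condition does not apply"),
                      label, d0, d1), call. = FALSE)
  }
  prof
}

#' @export
print.capform_profile <- function(x, ...) {
  cat(sprintf("<capform_profile '%s'>  theta(0.5)=%g\n", x$label,
              x$fun(0.5)))
  invisible(x)
}

#' Polynomial bump profiles theta_m(y) = A_m y^m (1-y)^m
#'
#' The family of unimodal disturbance profiles used throughout: symmetric
#' bumps centered at `y = 1/2`, normalized to unit integral by
#' `A_m = 1 / B(m+1, m+1)` (Beta function). The quartic member `m = 2` has
#' `A = 30`; `m = 3` has `A = 140`. For `m = 1` the endpoint derivatives do
#' not vanish (`theta'(0) = 6`), so that member is admitted with a warning
#' rather than rejected -- it is useful when exploring how steeper initial
#' gradients drive bimodal cell distributions.
#'
#' @param m Positive integer exponent.
#' @return A [initial_profile()] object with closed-form derivatives and an
#'   `A` attribute holding the normalization constant.
#' @examples
#' th <- bump_profile(2)
#' attr(th, "A")        # 30
#' th$fun(0.5)          # 30/16 = 1.875
#' @export
bump_profile <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer (m >= 1)", call. = FALSE)
  m <- as.integer(m)
  A <- 1 / beta(m + 1, m + 1)
  fun <- function(y) A * y^m * (1 - y)^m
  deriv <- function(y) A * m * y^(m - 1) * (1 - y)^(m - 1) * (1 - 2 * y)
  deriv2 <- if (m == 1L) {
    function(y) rep(-2 * A, length(y))
  } else {
    function(y) {
      A * (m * (m - 1) * y^(m - 2) * (1 - y)^m -
             2 * m^2 * y^(m - 1) * (1 - y)^(m - 1) +
             m * (m - 1) * y^m * (1 - y)^(m - 2))
    }
  }
  prof <- initial_profile(fun, deriv, deriv2,
                          label = sprintf("bump-m%d", m), check = TRUE)
  attr(prof, "A") <- A
  attr(prof, "m") <- m
  prof
}
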