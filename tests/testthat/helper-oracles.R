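# Independent oracles used to cross-check closed forms and solvers.
# These deliberately share no code with the package internals.

# Duhamel mode-sum solution of the transient linearized cell problem:
# n_t = D [n_yy - g(t) theta''(y)], n(y,0)=0, Neumann walls, with
# g(t) = rho1(1 - e^(-lambda t)) + rho2 mu [1/beta - e^(-lambda t)/(beta-lambda)
#        + lambda e^(-beta t)/(beta(beta-lambda))].
# Each cosine mode obeys a scalar linear ODE integrated in closed form.
duhamel_oracle <- function(y, t, theta_fun, rho1, rho2, mu, beta, lambda,
                           D_eta, Nk = 60) {
  K <- rho1 + rho2 * mu / beta
  P <- -(rho1 + rho2 * mu / (beta - lambda))
  Q <- rho2 * mu * lambda / (beta * (beta - lambda))
  n <- rep(0, length(y))
  for (k in seq_len(Nk)) {
    bk <- 2 * stats::integrate(function(s) theta_fun(s) * cos(k * pi * s),
                               0, 1, rel.tol = 1e-12)$value
    dk <- -k^2 * pi^2 * bk
    mu_k <- k^2 * pi^2 * D_eta
    conv <- function(a) (exp(-a * t) - exp(-mu_k * t)) / (mu_k - a)
    integ <- K * (1 - exp(-mu_k * t)) / mu_k + P * conv(lambda) + Q * conv(beta)
    n <- n + (-D_eta * dk * integ) * cos(k * pi * y)
  }
  n
}

# brute-force ODE integration of phi_t + beta phi = mu theta (1 - e^(-lambda t))
phi_ode_oracle <- function(y, t_end, theta_fun, lambda, beta, mu) {
  th <- theta_fun(y)
  out <- deSolve::ode(y = rep(0, length(y)), times = c(0, t_end),
                      func = function(t, phi, parms) {
                        list(-beta * phi + mu * th * (1 - exp(-lambda * t)))
                      }, parms = NULL, rtol = 1e-11, atol = 1e-13)
  out[2, -1]
}

# symmetric-difference numerical derivative
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# trapezoid weights on a uniform grid over [0, 1]
trap_w <- function(J) {
  h <- 1 / (J - 1)
  c(h / 2, rep(h, J - 2), h / 2)
}
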