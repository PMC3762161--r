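theta2 <- bump_profile(2)

test_that("factor and enzyme fractions exchange mass conservatively", {
  y <- c(0.1, 0.3, 0.5, 0.7)
  expect_equal(solve_w(y, 0, theta2, 20), theta2$fun(y))
  expect_equal(solve_xi(y, 0, theta2, 20), rep(0, 4))
  # direct evaluation at the example parameters
  expect_equal(solve_w(0.5, 0.1, theta2, 20), 1.875 * exp(-2))
  # conservation identity w + xi = theta at arbitrary points and times
  for (t in c(0.07, 0.3, 2)) {
    expect_equal(solve_w(y, t, theta2, 20) + solve_xi(y, t, theta2, 20),
                 theta2$fun(y))
  }
  # decay / saturation limits
  expect_lt(max(solve_w(y, 5, theta2, 20)), 1e-40)
  expect_equal(solve_xi(y, 5, theta2, 20), theta2$fun(y), tolerance = 1e-30)
})

test_that("fibronectin deficit matches an independent ODE integration", {
  y <- seq(0, 1, by = 0.1)
  expect_equal(solve_phi(y, 0, theta2, 20, 10, 5), rep(0, length(y)))
  # long-time plateau mu theta / beta
  expect_equal(solve_phi(y, 10, theta2, 20, 10, 5),
               5 * theta2$fun(y) / 10, tolerance = 1e-12)
  # brute-force integration of phi_t + beta phi = mu theta (1 - e^(-lambda t))
  ph_num <- phi_ode_oracle(y, 0.2, theta2$fun, lambda = 20, beta = 10, mu = 5)
  expect_equal(solve_phi(y, 0.2, theta2, 20, 10, 5), unname(ph_num),
               tolerance = 1e-8)
})

test_that("confluent branch takes over smoothly when beta ~ lambda", {
  y <- c(0.25, 0.5)
  # exactly degenerate rates: closed confluent form vs ODE oracle
  ph <- solve_phi(y, 0.15, theta2, lambda = 10, beta = 10, mu = 5)
  ph_num <- phi_ode_oracle(y, 0.15, theta2$fun, lambda = 10, beta = 10, mu = 5)
  expect_equal(ph, unname(ph_num), tolerance = 1e-8)
  # near-degenerate generic branch agrees with the confluent one
  ph_near <- solve_phi(y, 0.15, theta2, lambda = 10 * (1 + 1e-5), beta = 10,
                       mu = 5)
  expect_equal(ph_near, ph, tolerance = 1e-4)
})

test_that("quadrature spectrum matches the quartic closed form", {
  sp <- fourier_spectrum(theta2, K = 0.1, N = 50)
  cf <- quartic_spectrum(K = 0.1, N = 50)
  expect_equal(sp$coefficients[1], -2 * 0.1)
  n <- 1:50
  even <- n[n %% 2 == 0]
  odd <- n[n %% 2 == 1]
  expect_equal(sp$coefficients[even + 1], cf$coefficients[even + 1],
               tolerance = 1e-9)
  expect_true(all(abs(sp$coefficients[odd + 1]) < 1e-10))
})

test_that("flat profiles project onto the constant mode only", {
  flat <- initial_profile(function(y) rep(1, length(y)),
                          function(y) rep(0, length(y)),
                          function(y) rep(0, length(y)), label = "flat")
  sp <- fourier_spectrum(flat, K = 0.3, N = 20)
  expect_equal(sp$coefficients[1], -0.6)
  expect_true(all(abs(sp$coefficients[-1]) < 1e-10))
})

test_that("series solution honors its initial, boundary and limit structure", {
  sp <- fourier_spectrum(theta2, K = 0.1, N = 200)
  y <- seq(0, 1, length.out = 101)
  # zero initial perturbation up to series truncation
  expect_lt(max(abs(series_n(y, 0, sp, theta2, 0.1, 0.25))), 1e-6)
  # long-time limit -K + K theta
  expect_equal(as.vector(series_n(y, 60, sp, theta2, 0.1, 0.25)),
               -0.1 + 0.1 * theta2$fun(y), tolerance = 1e-12)
  # Neumann walls: odd reflection symmetry of every retained mode means the
  # one-sided slope at the wall vanishes as h -> 0 faster than h
  h <- 1e-5
  for (t in c(0.05, 1)) {
    nw <- series_n(c(0, h, 1 - h, 1), t, sp, theta2, 0.1, 0.25)
    expect_lt(abs(nw[2] - nw[1]) / h, 1e-3)
    expect_lt(abs(nw[4] - nw[3]) / h, 1e-3)
  }
  # zero spatial mean at all times (quadrature)
  for (t in c(0.01, 0.1, 1, 10)) {
    m <- stats::integrate(function(s)
      as.vector(series_n(s, t, sp, theta2, 0.1, 0.25)), 0, 1,
      rel.tol = 1e-10)$value
    expect_lt(abs(m), 1e-8)
  }
  # label mismatch is refused
  expect_error(series_n(y, 0.1, sp, bump_profile(3), 0.1, 0.25), "profile")
  expect_error(series_n(y, 0.1, sp, theta2, 0.2, 0.25), "K")
})

test_that("approach to the steady profile is bounded by the slowest mode", {
  sp <- fourier_spectrum(theta2, K = 0.1, N = 200)
  y <- seq(0, 1, length.out = 101)
  ninf <- -0.1 + 0.1 * theta2$fun(y)
  C2 <- sp$coefficients[3]
  dev_prev <- Inf
  for (t in c(0.2, 0.4, 0.8, 1.2)) {
    dev <- max(abs(as.vector(series_n(y, t, sp, theta2, 0.1, 0.25)) - ninf))
    expect_lt(dev, 1.05 * abs(C2) * exp(-4 * pi^2 * 0.25 * t))
    expect_lt(dev, dev_prev)
    dev_prev <- dev
  }
})

test_that("series residual satisfies the homogeneous heat equation", {
  # the substituted field u = n - K theta solves u_t = D u_yy; check the
  # residual of n itself by finite differences against the forcing-free form
  sp <- fourier_spectrum(theta2, K = 0.1, N = 200)
  D <- 0.25
  y <- seq(0.1, 0.9, by = 0.1)
  t <- 0.05
  dt <- 1e-6; dy <- 1e-4
  nf <- function(yy, tt) as.vector(series_n(yy, tt, sp, theta2, 0.1, D))
  n_t <- (nf(y, t + dt) - nf(y, t - dt)) / (2 * dt)
  n_yy <- (nf(y + dy, t) - 2 * nf(y, t) + nf(y - dy, t)) / dy^2
  resid <- n_t - D * (n_yy - 0.1 * theta2$deriv2(y))
  expect_lt(max(abs(resid)), 1e-3)
})

test_that("assembled densities obey the perturbation structure", {
  pr <- load_preset("example2013")
  y <- seq(0, 1, length.out = 51)
  f0 <- assemble_fields(y, 0, pr$config, pr$params)
  expect_equal(f0$v, 0.05 * theta2$fun(y))
  expect_equal(f0$c, rep(0, 51))
  expect_equal(f0$f, rep(1, 51))
  expect_equal(f0$eta, rep(1, 51), tolerance = 1e-6)
  # worked-example value at the bump center
  f1 <- assemble_fields(0.5, 0.1, pr$config, pr$params)
  expect_equal(f1$v, 0.05 * 1.875 * exp(-2))
  # exact exchange identity and physical ranges at several times
  for (t in c(0.02, 0.1, 1)) {
    fl <- assemble_fields(y, t, pr$config, pr$params)
    expect_equal(fl$v + fl$c, 0.05 * theta2$fun(y))
    expect_true(all(fl$f > 0 & fl$f <= 1))
    expect_true(all(fl$eta > 0))
  }
  # a perturbation too large to stay positive is flagged
  big <- perturbation_config(3, theta2, K = 0.1)
  expect_warning(assemble_fields(y, 1, big, pr$params), "perturbation regime")
})

test_that("stable steady state is the long-time series limit", {
  sp <- fourier_spectrum(theta2, K = 0.1, N = 200)
  B <- stable_B(sp)
  expect_equal(B, -0.1, tolerance = 1e-10)
  y <- seq(0, 1, length.out = 41)
  expect_equal(steady_state(y, B, 0.1, theta2),
               as.vector(series_n(y, 80, sp, theta2, 0.1, 0.25)),
               tolerance = 1e-12)
  # K = 0: flat profile; theta vanishing at the walls
  expect_equal(steady_state(y, 0.7, 0, theta2), rep(0.7, 41))
  expect_equal(steady_state(0, 0, 0.1, theta2), 0)
  # B = -K holds for any unit-normalized profile
  th3 <- bump_profile(3)
  expect_equal(stable_B(fourier_spectrum(th3, 0.25, 50)), -0.25,
               tolerance = 1e-10)
})
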