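test_that("input_rate reproduces basal and bolus arithmetic", {
  expect_equal(input_rate(c(0, 100, 5000), dosing_schedule()), c(0, 0, 0))

  b <- dosing_schedule(bolus = data.frame(start = 1080, duration = 1,
                                          dose = 8))
  expect_equal(input_rate(1080.5, b), 8000)   # 8 U over 1 min = 8000 mU/min
  expect_equal(input_rate(1082, b), 0)
  expect_equal(input_rate(1080, b), 8000)     # right-continuous at the start

  basal <- dosing_schedule(basal = data.frame(start = 0, end = 1440,
                                              rate = 0.6))
  expect_equal(input_rate(100, basal), 10)    # 600 mU/h over 60 min
  # overlapping bolus on top of basal adds the two rates
  both <- dosing_schedule(basal = data.frame(start = 0, end = 1440,
                                             rate = 0.6),
                          bolus = data.frame(start = 90, duration = 20,
                                             dose = 4))
  expect_equal(input_rate(100, both), 10 + 4000 / 20)
})

test_that("integrator matches the analytic solution on random schedules", {
  d0 <- dosing_schedule()
  s0 <- integrate_compartments(d0, 50, c(0, 10, 100))
  expect_equal(s0$Q1, c(0, 0, 0))
  expect_equal(s0$Q2, c(0, 0, 0))

  set.seed(401)
  worst <- 0
  for (r in 1:25) {
    sched <- random_schedule()
    tmax <- runif(1, 20, 120)
    times <- sort(runif(12, 0, 1300))
    num <- integrate_compartments(sched, tmax, times)
    exact <- closed_form_compartments(sched, tmax, times)
    worst <- max(worst,
                 max_rel_err(c(num$Q1, num$Q2), c(exact$Q1, exact$Q2)))
  }
  expect_lt(worst, 1e-5)
})

test_that("impulse response of Q2 peaks at t_max with value D/e", {
  # 8 U over 1 min approximates an impulse: cascade peak D * exp(-1) at t_max
  d <- dosing_schedule(bolus = data.frame(start = 0, duration = 1, dose = 8))
  tmax <- 50
  s <- integrate_compartments(d, tmax, c(45, 49, 50, 51, 55))
  expect_lt(abs(s$Q2[3] - 8000 * exp(-1)) / (8000 * exp(-1)), 0.01)
  # exact impulse-cascade shape via the closed form with a short pulse
  expect_equal(closed_form_compartments(d, tmax, 50)$Q2, s$Q2[3],
               tolerance = 1e-6)
  # with a near-instantaneous pulse the peak sits at t_max itself
  di <- dosing_schedule(bolus = data.frame(start = 0, duration = 0.01,
                                           dose = 8))
  grid <- seq(45, 55, by = 0.5)
  si <- integrate_compartments(di, tmax, grid)
  expect_equal(grid[which.max(si$Q2)], tmax)
})

test_that("constant infusion approaches the steady state rate * t_max", {
  d <- dosing_schedule(basal = data.frame(start = 0, end = 10000,
                                          rate = 0.6))  # 10 mU/min
  s <- integrate_compartments(d, 50, 5000)
  expect_equal(s$Q1, 500, tolerance = 1e-4)
  expect_equal(s$Q2, 500, tolerance = 1e-4)
})

test_that("mass balance holds: input = Q1 + Q2 + cumulative elimination", {
  sched <- dosing_schedule(
    basal = data.frame(start = c(0, 300), end = c(200, 500),
                       rate = c(1.2, 0.6)),
    bolus = data.frame(start = 100, duration = 5, dose = 6))
  tmax <- 40
  grid <- seq(0, 700, by = 0.25)
  sol <- closed_form_compartments(sched, tmax, grid)
  elim <- cumsum((sol$Q2[-1] + sol$Q2[-length(grid)]) / 2 / tmax) * 0.25
  total_in <- function(t) {
    inp <- 1.2 * 1000 / 60 * pmin(pmax(t, 0), 200) +
      0.6 * 1000 / 60 * pmax(pmin(t, 500) - 300, 0) +
      6000 / 5 * pmax(pmin(t, 105) - 100, 0)
    inp
  }
  lhs <- total_in(grid[-1])
  rhs <- sol$Q1[-1] + sol$Q2[-1] + elim
  expect_lt(max(abs(lhs - rhs) / pmax(lhs, 1)), 1e-3)
})

test_that("numerical integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  sched <- dosing_schedule(
    basal = data.frame(start = 50, end = 400, rate = 0.9),
    bolus = data.frame(start = 200, duration = 2, dose = 7))
  tmax <- 60
  times <- c(0, 60, 199, 210, 350, 500)
  mine <- integrate_compartments(sched, tmax, times, rtol = 1e-8,
                                 atol = 1e-8)
  rate_fn <- function(t) input_rate(t, sched)
  deriv <- function(t, y, parms) {
    list(c(rate_fn(t) - y[1] / tmax, (y[1] - y[2]) / tmax))
  }
  ref <- deSolve::ode(c(0, 0), sort(unique(c(times, 50, 400, 200, 202))),
                      deriv, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  ref_q <- ref[match(times, ref[, 1]), 2:3]
  expect_lt(max_rel_err(c(mine$Q1, mine$Q2), c(ref_q[, 1], ref_q[, 2])),
            1e-4)
})

test_that("predicted concentration combines efflux and residual drift", {
  ctx <- profile_context(wt = 70, t_end = 300)
  p0 <- kinetic_params(50, 0.02, a = 0, b = 12)
  expect_equal(predicted_concentration(p0, ctx, 100, Q2 = 0), 12)
  p1 <- kinetic_params(50, 0.02, a = 1, b = 0)
  expect_equal(predicted_concentration(p1, ctx, 310, Q2 = 0), 10)
  # steady state: mu = conv * rate / (wt * MCR), independent of t_max
  for (tmax in c(30, 50, 90)) {
    p <- kinetic_params(tmax, 0.02)
    expect_equal(predicted_concentration(p, ctx, 0, Q2 = 10 * tmax),
                 6 * 10 / (70 * 0.02), tolerance = 1e-12)
  }
})

test_that("log-likelihood matches direct Gaussian computation", {
  ctx <- profile_context(wt = 70, t_end = 300)
  d <- dosing_schedule()

  # single observation at the mean, kappa = 1, lambda = 0
  p <- kinetic_params(50, 0.02, a = 0, b = 20)
  obs1 <- list(times = 10, conc = 20)
  expect_equal(log_likelihood(obs1, p, nuisance_params(1, 0), ctx, d),
               -0.5 * log(2 * pi))

  # homoscedastic case against a hand-rolled sum on 3 fabricated points
  p2 <- kinetic_params(50, 0.02, a = 0.5, b = 10)
  obs <- list(times = c(100, 200, 290), conc = c(-90, -45, 7))
  mu <- 0.5 * (obs$times - 300) + 10
  expected <- sum(-0.5 * (log(2 * pi * 4) + (obs$conc - mu)^2 / 4))
  expect_equal(log_likelihood(obs, p2, nuisance_params(2, 0), ctx, d),
               expected)

  # multiplicative-only model: scaling y and mu by c shifts ll by -n log(c)
  cfac <- 3.7
  nu <- nuisance_params(0, 0.3)
  p_scaled <- kinetic_params(50, 0.02, a = 0.5 * cfac, b = 10 * cfac)
  obs_scaled <- list(times = obs$times, conc = obs$conc * cfac)
  expect_equal(log_likelihood(obs_scaled, p_scaled, nu, ctx, d),
               log_likelihood(obs, p2, nu, ctx, d) - 3 * log(cfac),
               tolerance = 1e-10)

  # permutation invariance
  perm <- c(2, 3, 1)
  expect_equal(
    log_likelihood(list(times = obs$times[perm], conc = obs$conc[perm]),
                   p2, nuisance_params(2, 0.1), ctx, d),
    log_likelihood(obs, p2, nuisance_params(2, 0.1), ctx, d))

  # degenerate variance: kappa = 0 and mu = 0
  p0 <- kinetic_params(50, 0.02, a = 0, b = 0)
  expect_error(
    log_likelihood(obs1, p0, nuisance_params(0, 0.5), ctx, d),
    "degenerate")
})
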