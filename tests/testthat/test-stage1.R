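# a hand-built profile with known kinetics, for calibration checks
known_profile <- function(seed, theta = c(55, 0.025, -0.03, 30),
                          kappa = 5, lam = 0.05) {
  set.seed(seed)
  sched <- dosing_schedule(
    basal = data.frame(start = 0, end = 1440, rate = 0.6),
    bolus = data.frame(start = 1080, duration = 1, dose = 9))
  tt <- sampling_times(1080, 1050, 1380)
  params <- kinetic_params(theta[1], theta[2], theta[3], theta[4])
  ctx <- profile_context(70, 1380, 1050)
  mu <- predicted_concentration(
    params, ctx, tt, integrate_compartments(sched, theta[1], tt)$Q2)
  y <- rnorm(length(tt), mu, sqrt(kappa^2 + lam^2 * mu^2))
  pk_profile(1, 1, "dinner", tt, y, sched, 70, 1380, 1050)
}

test_that("stored draw counts follow the thinning arithmetic", {
  p <- known_profile(1)
  cfg <- stage1_config(burn_in = 500, iterations = 2000, thin = 100,
                       n_chains = 2)
  fit <- run_stage1(p, cfg, seed = 3)
  expect_equal(nrow(fit$draws), 2000 / 100 * 2)
  expect_equal(colnames(fit$draws),
               c("t_max", "mcr", "a", "b", "kappa", "lam"))
})

test_that("stored draws respect the stage-1 prior supports", {
  p <- known_profile(2)
  fit <- run_stage1(p, quick_s1(), seed = 5)
  pr <- stage1_prior()
  d <- fit$draws
  expect_true(all(d[, "t_max"] > pr$t_max[1] & d[, "t_max"] < pr$t_max[2]))
  expect_true(all(d[, "mcr"] > 0 & d[, "mcr"] < pr$mcr[2]))
  expect_true(all(d[, "kappa"] > 0 & d[, "kappa"] < 100))
  expect_true(all(d[, "lam"] > 0 & d[, "lam"] < 1))
})

test_that("pathological flat data still yields a complete run", {
  tt <- seq(1100, 1350, by = 25)
  p <- pk_profile(1, 1, "dinner", tt, rep(20, length(tt)),
                  dosing_schedule(), 70, 1380, 1050)
  fit <- run_stage1(p, stage1_config(500, 1500, 10, 1), seed = 1)
  expect_false(is.null(fit$draws))
  expect_true(all(is.finite(fit$draws)))
})

test_that("profiles with too few observations are refused", {
  p <- pk_profile(1, 1, "dinner", c(1100, 1120, 1140, 1160, 1180),
                  rep(20, 5), dosing_schedule(), 70, 1380, 1050)
  expect_error(run_stage1(p), "fewer than 6")
})

test_that("posterior intervals are calibrated for data from the model", {
  # calibration under the true model: each replicate draws its own kinetic
  # truth from the population scale, then checks the 95% intervals for both
  # kinetic parameters; at least 90% of the 40 checks must cover
  hits <- 0
  for (r in 1:20) {
    set.seed(7000 + r)
    th <- c(exp(rnorm(1, log(55), 0.15)), exp(rnorm(1, log(0.025), 0.15)),
            rnorm(1, -0.03, 0.03), rnorm(1, 30, 8))
    p <- known_profile(9000 + r, theta = th)
    fit <- run_stage1(p, stage1_config(2500, 10000, 10, 1), seed = 800 + r)
    qt <- quantile(fit$draws[, "t_max"], c(0.025, 0.975))
    qm <- quantile(fit$draws[, "mcr"], c(0.025, 0.975))
    hits <- hits + (qt[1] <= th[1] && th[1] <= qt[2]) +
      (qm[1] <= th[2] && th[2] <= qm[2])
  }
  expect_gte(hits, 36)
})

test_that("unidentifiable kinetics pile at a prior bound and get flagged", {
  # true MCR far above the physiological ceiling: the fitted MCR saturates
  p <- known_profile(11, theta = c(55, 0.6, 0, 10), kappa = 2, lam = 0.02)
  fit <- run_stage1(p, quick_s1(), seed = 9)
  expect_true(fit$flag)
})

test_that("BGR statistic separates mixed from unmixed chains", {
  set.seed(42)
  same <- matrix(rnorm(400), 200, 2)
  expect_true(all(bgr_diagnostic(list(same, same)) <= 1))

  c1 <- cbind(rnorm(200, 0, 1)); c2 <- cbind(rnorm(200, 10, 1))
  expect_gt(bgr_diagnostic(list(c1, c2))[1], 1.1)

  # affine invariance under a joint transformation
  a <- matrix(rnorm(600), 300, 2); b <- matrix(rnorm(600, 0.2), 300, 2)
  r1 <- bgr_diagnostic(list(a, b))
  r2 <- bgr_diagnostic(list(a * 3 - 7, b * 3 - 7))
  expect_equal(r1, r2, tolerance = 1e-12)

  expect_error(bgr_diagnostic(list(a)), "length")
})

test_that("stage-1 marginals match a dense-grid posterior on the linear
           surrogate", {
  # no dosing and lambda fixed at zero: mu = a (t - t_end) + b, so the
  # posterior of (a, b, kappa) is available by cubature on a grid
  set.seed(77)
  tt <- seq(1060, 1370, by = 28)
  a0 <- -0.05; b0 <- 25; k0 <- 3
  y <- rnorm(length(tt), a0 * (tt - 1380) + b0, k0)
  p <- pk_profile(1, 1, "dinner", tt, y, dosing_schedule(), 70, 1380, 1050)
  fit <- run_stage1(p, stage1_config(4000, 100000, 10, 1), seed = 13,
                    fix_lambda = TRUE)
  expect_equal(nrow(fit$draws), 1e4)

  X <- cbind(tt - 1380, 1)
  bhat <- solve(crossprod(X), crossprod(X, y))
  se <- sqrt(diag(solve(crossprod(X))) * k0^2)
  ga <- seq(bhat[1] - 8 * se[1], bhat[1] + 8 * se[1], length.out = 81)
  gb <- seq(bhat[2] - 8 * se[2], bhat[2] + 8 * se[2], length.out = 81)
  gk <- seq(k0 / 4, k0 * 4, length.out = 81)
  lp <- array(NA_real_, c(81, 81, 81))
  for (ia in 1:81) for (ib in 1:81) {
    rss <- sum((y - ga[ia] * (tt - 1380) - gb[ib])^2)
    lp[ia, ib, ] <- -length(tt) * log(gk) - rss / (2 * gk^2) +
      dnorm(ga[ia], 0, 100, log = TRUE) + dnorm(gb[ib], 0, 100, log = TRUE)
  }
  post <- exp(lp - max(lp))
  marg <- function(dim, grid) {
    m <- apply(post, dim, sum); m <- m / sum(m)
    list(grid = grid, cdf = cumsum(m) - m / 2)
  }
  ma <- marg(1, ga); mk <- marg(3, gk)
  expect_lt(ks_vs_grid(fit$draws[, "a"], ma$grid, ma$cdf), 0.05)
  expect_lt(ks_vs_grid(fit$draws[, "kappa"], mk$grid, mk$cdf), 0.05)
})

test_that("fit diagnostics standardize residuals correctly", {
  theta <- c(55, 0.025, -0.03, 30)
  p <- known_profile(5, theta = theta)
  truth_row <- matrix(c(theta, 5, 0.05), 1,
                      dimnames = list(NULL, c("t_max", "mcr", "a", "b",
                                              "kappa", "lam")))
  # noise-free data at the truth: residuals identically zero
  mu <- {
    sched <- p$dosing
    params <- kinetic_params(theta[1], theta[2], theta[3], theta[4])
    predicted_concentration(
      params, profile_context(70, 1380, 1050), p$times,
      integrate_compartments(sched, theta[1], p$times)$Q2)
  }
  clean <- pk_profile(1, 1, "dinner", p$times, mu, p$dosing, 70, 1380, 1050)
  diag0 <- fit_diagnostics(clean, truth_row)
  expect_equal(diag0$resid_std, rep(0, length(mu)), tolerance = 1e-8)

  # noisy data at the truth: standardized residuals ~ N(0, 1), and the 95%
  # predictive band captures about 95% of observations (pooled)
  inside <- 0; nobs <- 0; resids <- numeric()
  truth_many <- truth_row[rep(1, 300), ]   # predictive band at fixed truth
  for (r in 1:6) {
    pr <- known_profile(500 + r, theta = theta)
    dg <- fit_diagnostics(pr, truth_many)
    resids <- c(resids, dg$resid_std)
    inside <- inside + sum(dg$observed >= dg$lo & dg$observed <= dg$hi)
    nobs <- nobs + nrow(dg)
  }
  expect_lt(abs(mean(resids)), 0.25)
  expect_lt(abs(sd(resids) - 1), 0.25)
  expect_gt(inside / nobs, 0.85)
})

test_that("the stage-1 store round-trips through delimited files", {
  st <- small_store()
  dir <- withr::local_tempdir()
  write_stage1_store(st, dir)
  back <- read_stage1_store(dir)
  expect_equal(names(back$entries), names(st$entries))
  for (id in names(st$entries))
    expect_equal(back$entries[[id]]$draws, st$entries[[id]]$draws,
                 tolerance = 1e-12)
  expect_equal(back$config$thin, st$config$thin)
})
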