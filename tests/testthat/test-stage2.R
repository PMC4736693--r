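test_that("Gibbs intercept full conditional matches a dense-grid posterior", {
  # toy: prior N(1, 2^2), three Gaussian children with sd 0.8
  children <- c(0.5, 1.5, 3.0)
  prec <- 1 / 4 + 3 / 0.8^2
  mean_an <- (1 / 4 + sum(children) / 0.8^2) / prec

  grid <- seq(-4, 6, length.out = 20001)
  lp <- dnorm(grid, 1, 2, log = TRUE) +
    vapply(grid, function(m) sum(dnorm(children, m, 0.8, log = TRUE)),
           numeric(1))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean_grid <- sum(grid * w)
  var_grid <- sum((grid - mean_grid)^2 * w)
  expect_equal(mean_grid, mean_an, tolerance = 1e-6)
  expect_equal(var_grid, 1 / prec, tolerance = 1e-5)

  set.seed(31)
  draws <- replicate(20000, gibbs_update_intercept(1, 2, sum(children), 3,
                                                   0.8))
  expect_equal(mean(draws), mean_an, tolerance = 0.01)
  expect_equal(sd(draws), sqrt(1 / prec), tolerance = 0.01)

  # vague prior, single child: full conditional centred on the child
  set.seed(32)
  d2 <- replicate(5000, gibbs_update_intercept(0, 1e8, 2.5, 1, 0.3))
  expect_equal(mean(d2), 2.5, tolerance = 0.02)
})

test_that("slice updates leave the sd full conditional invariant", {
  # 10 children with fixed sum of squares: compare the chain's long-run
  # distribution with the analytic density sigma^{-n} exp(-S / 2 sigma^2)
  n <- 10; S <- 14
  set.seed(41)
  cur <- 1; draws <- numeric(6000)
  for (i in seq_along(draws)) {
    cur <- slice_update_sd(cur, S, n)
    draws[i] <- cur
  }
  grid <- seq(1e-3, 8, length.out = 4000)
  dens <- exp(-n * log(grid) - S / (2 * grid^2))
  dens <- dens / sum(dens)
  expect_lt(ks_vs_grid(draws, grid, cumsum(dens) - dens / 2), 0.05)
  expect_true(all(draws > 0 & draws < 100))

  # support respected from extreme starting points
  set.seed(42)
  expect_true(slice_update_sd(99.9, 0.01, 2) < 100)
  expect_true(slice_update_sd(1e-4, 50, 2) > 0)

  # no children: the prior itself
  set.seed(43)
  pri <- replicate(4000, slice_update_sd(1, 0, 0))
  expect_lt(ks_vs_grid(pri, c(0, 100), c(0, 1)), 0.05)
})

test_that("resampling acceptance reduces to the population-density ratio", {
  # two stored draws differing only in `a`: flat components cancel and the
  # ratio is the N(0,1) density ratio exp(-1/2), up to the (tiny) stage-1
  # N(0,100^2) prior correction for `a`
  draws <- cbind(t_max = c(50, 50), mcr = c(0.02, 0.02), a = c(0, 1),
                 b = c(0, 0), kappa = c(5, 5), lam = c(0.1, 0.1))
  entry <- list(draws = draws)
  eta <- c(log(50), log(0.02), 0, 0)
  sigma <- c(1, 1, 1, 1)
  seen <- c(FALSE, FALSE)
  for (s in 1:50) {
    set.seed(s)
    res <- resample_profile_params(entry, idx = 1, eta, sigma)
    if (res$proposed == 1) {
      expect_equal(res$log_ratio, 0)          # same state: always accept
      expect_true(res$accepted)
      seen[1] <- TRUE
    } else {
      corr <- dnorm(0, 0, 100, log = TRUE) - dnorm(1, 0, 100, log = TRUE)
      expect_equal(res$log_ratio, -0.5 + corr, tolerance = 1e-12)
      seen[2] <- TRUE
    }
    if (all(seen)) break
  }
  expect_true(all(seen))
  expect_error(resample_profile_params(list(draws = draws[0, , drop = FALSE]),
                                       1, eta, sigma), "empty")
})

test_that("reversible-jump ratios match a first-principles computation", {
  set.seed(51)
  n <- 30
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  resid0 <- rnorm(n, 0.8 * X[, 2], 0.5)
  cols <- 1:4; sig <- 0.5; psd <- 1.2

  # forced delete from {2} with coefficient b0: the acceptance ratio must
  # equal the posterior ratio times the uniform-menu proposal ratio
  b0 <- 0.7
  set.seed(52)
  res <- rj_update_group(list(gamma = 2L, beta = b0), cols, X, resid0, sig,
                         psd, "binary", move = "delete")
  ll1 <- sum(dnorm(resid0 - X[, 2] * b0, 0, sig, log = TRUE))
  ll0 <- sum(dnorm(resid0, 0, sig, log = TRUE))
  # menus: q=1 -> {add, delete, refresh, swap}; q=0 -> {add}
  lr_oracle <- (ll0 - ll1) +
    (model_prior_logpmf("binary", 0, integer(), 4) -
       model_prior_logpmf("binary", 1, 2L, 4)) +
    (log(1 / 1) + log(1 / 4)) - (log(1 / 4) + log(1 / 1))
  expect_equal(res$log_ratio, lr_oracle, tolerance = 1e-12)

  # interaction group never exceeds three indicators
  sel <- list(gamma = integer(), beta = numeric())
  set.seed(53)
  qs <- integer(3000)
  for (i in seq_along(qs)) {
    upd <- rj_update_group(sel, cols, X, resid0, sig, psd, "interaction",
                           loglik_weight = 0)
    sel <- upd$sel
    qs[i] <- length(sel$gamma)
  }
  expect_lte(max(qs), 3)

  # refresh is a Gibbs move: with data strongly favouring column 2, the
  # refreshed coefficient concentrates near the generating value
  set.seed(54)
  bs <- replicate(300, rj_update_group(list(gamma = 2L, beta = 0), cols, X,
                                       resid0, sig, psd, "binary",
                                       move = "refresh")$sel$beta)
  expect_lt(abs(mean(bs) - 0.8), 0.15)
})

test_that("stage 2 is deterministic and never touches the ODE solver", {
  st <- small_store()
  ds <- small_trial()$dataset
  spec <- model_spec("one")

  ode_call_reset()
  f1 <- run_stage2(st, ds, spec, quick_s2(), seed = 77)
  expect_equal(ode_call_count(), 0)

  f2 <- run_stage2(st, ds, spec, quick_s2(), seed = 77)
  expect_identical(f1$draws$phi, f2$draws$phi)
  expect_identical(f1$draws$theta_idx, f2$draws$theta_idx)

  f3 <- run_stage2(st, ds, spec, quick_s2(), seed = 78)
  expect_false(identical(f1$draws$phi, f3$draws$phi))
})

test_that("stage-2 decisions ignore the stored nuisance parameters", {
  st <- small_store()
  ds <- small_trial()$dataset
  spec <- model_spec("one")
  f1 <- run_stage2(st, ds, spec, quick_s2(), seed = 5)

  st2 <- st
  set.seed(999)
  for (id in names(st2$entries)) {
    H <- nrow(st2$entries[[id]]$draws)
    st2$entries[[id]]$draws[, "kappa"] <- runif(H, 0, 100)
    st2$entries[[id]]$draws[, "lam"] <- runif(H, 0, 1)
  }
  f2 <- run_stage2(st2, ds, spec, quick_s2(), seed = 5)
  expect_identical(f1$draws$theta_idx, f2$draws$theta_idx)
  expect_identical(f1$draws$phi, f2$draws$phi)
})

test_that("a single stored draw pins the profile parameters only", {
  st <- small_store()
  for (id in names(st$entries))
    st$entries[[id]]$draws <- st$entries[[id]]$draws[1, , drop = FALSE]
  f <- run_stage2(st, small_trial()$dataset, model_spec("one"), quick_s2(),
                  seed = 3)
  expect_true(all(f$draws$theta_idx == 1L))
  expect_gt(sd(f$draws$phi[, 1]), 0)
  expect_gt(sd(f$draws$sigma_theta[, 4]), 0)
})

test_that("variance decomposition recovers equal woman/residual shares", {
  des <- trial_design(n_women = 14, visits_per_woman = 2, meals = "dinner",
                      level = "two",
                      sigma_theta = c(0.15, 0.12, 0.03, 6),
                      sigma_psi = c(0.15, 0.12, 0.03, 6),
                      beta = list(), covariates = FALSE)
  tr <- memo("two_level_trial", function() generate_trial(des, seed = 31))
  st <- memo("two_level_store", function()
    run_stage1_all(tr$dataset, quick_s1(), seed = 41))

  f2 <- run_stage2(st, tr$dataset, model_spec("two"),
                   stage2_config(3000, 1000, 2), seed = 8)
  vd <- variance_decomposition(f2)
  expect_equal(colnames(vd$proportions), c("woman", "residual"))
  expect_equal(unname(rowSums(vd$proportions)), rep(1, 4))
  # equal true components for log t_max: the posterior of the woman share
  # must cover the true share 1/2
  share_w <- f2$draws$sigma_psi[, 1]^2 /
    (f2$draws$sigma_psi[, 1]^2 + f2$draws$sigma_theta[, 1]^2)
  qs <- quantile(share_w, c(0.025, 0.975))
  expect_true(qs[1] <= 0.5 && 0.5 <= qs[2])

  # three-level visit fit on the same data: with one profile per visit the
  # visit and residual components are confounded, but the woman share and
  # the combined within-woman share must agree with the two-level fit
  f3 <- run_stage2(st, tr$dataset, model_spec("threeV"),
                   stage2_config(3000, 1000, 2), seed = 9)
  vd3 <- variance_decomposition(f3)
  expect_equal(unname(rowSums(vd3$proportions)), rep(1, 4))
  expect_lt(abs(vd3$proportions["t_max", "woman"] -
                  vd$proportions["t_max", "woman"]), 0.15)

  # one-level fit: the single component carries everything
  f1 <- run_stage2(st, tr$dataset, model_spec("one"), quick_s2(), seed = 10)
  vd1 <- variance_decomposition(f1)
  expect_equal(unname(vd1$proportions[, "residual"]), rep(1, 4))
})

test_that("effect summaries are conditional on inclusion", {
  S <- 40
  incl <- array(FALSE, c(S, 4, 2), dimnames = list(NULL, PARAM <-
    c("t_max", "mcr", "a", "b"), c("x1", "study2_breakfast")))
  beta <- array(NA_real_, dim(incl), dimnames = dimnames(incl))
  incl[, 1, 1] <- TRUE                   # always included on t_max
  beta[, 1, 1] <- 0.017
  incl[1:10, 3, 2] <- TRUE               # sometimes included on a
  beta[1:10, 3, 2] <- 0.2
  fit <- structure(list(
    draws = list(inclusion = incl, beta = beta,
                 phi = matrix(c(log(55), log(0.025), 0, 30)[col(matrix(1, S, 4))],
                              S, 4)),
    spec = model_spec("one", covariates = TRUE)), class = "stage2_fit")

  ip <- inclusion_probabilities(fit)
  expect_equal(ip[1, "x1"], 1)
  expect_equal(ip[3, "study2_breakfast"], 0.25)
  expect_equal(ip[2, "x1"], 0)

  ce <- conditional_effect_summaries(fit)
  r <- ce$effects[ce$effects$parameter == "t_max" &
                    ce$effects$covariate == "x1", ]
  expect_equal(r$mean, 0.017)
  expect_equal(r$pct_mean, 100 * (exp(0.017) - 1))   # ~ +1.7% per unit
  never <- ce$effects[ce$effects$parameter == "mcr" &
                        ce$effects$covariate == "x1", ]
  expect_true(is.na(never$mean))
  expect_equal(never$p_include, 0)

  # typical value for a cell: phi plus the cell coefficient when selected
  ty <- ce$typical[ce$typical$parameter == "a" &
                     ce$typical$cell == "study2_breakfast", ]
  expect_equal(ty$mean, mean(c(rep(0.2, 10), rep(0, 30))))
})
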