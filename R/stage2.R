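#' Stage-2 run configuration
#'
#' @param iterations total sweeps.
#' @param burn_in sweeps discarded.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param slice_w initial slice-sampling interval width for sd updates.
#' @param store_effects keep per-draw woman/visit/meal intercepts (needed by
#'   the cross-validation module).
#' @export
stage2_config <- function(iterations = 4000, burn_in = 1000, thin = 2,
                          slice_w = 1, store_effects = TRUE) {
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1)
  list(iterations = iterations, burn_in = burn_in, thin = thin,
       slice_w = slice_w, store_effects = store_effects)
}

# ---------------------------------------------------------------------------
# update kernels
# ---------------------------------------------------------------------------

#' Conjugate Gibbs draw for a Gaussian intercept node
#'
#' All intercept nodes of the hierarchy (global, woman, visit, mealtime)
#' have Normal full conditionals: with prior `N(m0, s0^2)` and `n` Gaussian
#' children with sd `s` summing to `child_sum`, the full conditional has
#' precision `1/s0^2 + n/s^2` and mean the precision-weighted average. For
#' t_max and MCR the children are on the log scale.
#'
#' @param prior_mean,prior_sd prior (parent) mean and sd.
#' @param child_sum sum of the children's (log-)values net of any covariate
#'   contribution.
#' @param n_children number of children.
#' @param child_sd children's sd.
#' @return one draw from the full conditional.
#' @export
gibbs_update_intercept <- function(prior_mean, prior_sd, child_sum,
                                   n_children, child_sd) {
  prec <- 1 / prior_sd^2 + n_children / child_sd^2
  mean <- (prior_mean / prior_sd^2 + child_sum / child_sd^2) / prec
  rnorm(length(mean), mean, sqrt(1 / prec))
}

#' Slice-sampling update for a standard deviation
#'
#' One stepping-out/shrinkage slice transition for an sd with uniform prior
#' on `(0, upper)` and `n` Gaussian children whose squared deviations sum to
#' `ssq`: the full conditional is proportional to
#' `sigma^{-n} exp(-ssq / (2 sigma^2))` on the support. The transition
#' leaves this distribution invariant and never proposes outside the
#' support.
#'
#' @param sigma current value.
#' @param ssq sum of squared child deviations.
#' @param n number of children (`n = 0` samples the uniform prior).
#' @param upper prior upper bound.
#' @param w initial slice interval width.
#' @export
slice_update_sd <- function(sigma, ssq, n, upper = 100, w = NULL) {
  if (n == 0) return(runif(1, 0, upper))
  logf <- function(s) {
    if (s <= 0 || s >= upper) return(-Inf)
    -n * log(s) - ssq / (2 * s^2)
  }
  if (is.null(w)) w <- sigma / 2 + 0.05
  y <- logf(sigma) + log(runif(1))
  lo <- sigma - runif(1) * w
  hi <- lo + w
  while (lo > 0 && logf(lo) > y) lo <- lo - w
  while (hi < upper && logf(hi) > y) hi <- hi + w
  lo <- max(lo, 0); hi <- min(hi, upper)
  repeat {
    prop <- runif(1, lo, hi)
    if (logf(prop) > y) return(prop)
    if (prop < sigma) lo <- prop else hi <- prop
  }
}

# log target (up to likelihood, which cancels) of a stored draw h for one
# profile: sum_l log p(theta_h[l] | eta_l, sigma_l) - log p1(theta_h), with
# the lognormal Jacobians and the N(0,100^2) stage-1 prior terms for a, b
# folded into the per-draw constant `base`
ttheta_base <- function(ttheta_draws) {
  -ttheta_draws[, 1] - ttheta_draws[, 2] -
    dnorm(ttheta_draws[, 3], 0, 100, log = TRUE) -
    dnorm(ttheta_draws[, 4], 0, 100, log = TRUE)
}

ttheta_logtarget <- function(tt, base, eta, sigma) {
  # tt: m x 4 rows on the modelling scale; eta: length-4; sigma: length-4
  s <- base
  for (l in 1:4) s <- s + dnorm(tt[, l], eta[l], sigma[l], log = TRUE)
  s
}

#' One resampling Metropolis-Hastings step for a profile's parameters
#'
#' Proposes a uniformly chosen stage-1 draw as the profile's new parameter
#' vector. Because the proposal is the stage-1 posterior, the profile
#' likelihood (and the nuisance priors for kappa, lambda) cancel from the
#' acceptance ratio, which reduces to the population-density ratio times the
#' stage-1 prior ratio — the uniform stage-1 components cancel within
#' support and the N(0, 100^2) components for a and b are included exactly.
#' kappa and lambda are never updated: the ratio does not depend on them.
#'
#' @param entry a stage-1 store entry (element of `store$entries`).
#' @param idx current draw index.
#' @param eta length-4 linear predictors for this profile (log scale for
#'   l = 1, 2).
#' @param sigma length-4 population residual sds.
#' @return list with the new `idx`, the `proposed` index, the `log_ratio`
#'   and whether the proposal was `accepted`.
#' @export
resample_profile_params <- function(entry, idx, eta, sigma) {
  H <- nrow(entry$draws)
  if (H < 1) stop("empty stage-1 store entry")
  tt <- entry$draws[, 1:4, drop = FALSE]
  tt[, 1] <- log(tt[, 1]); tt[, 2] <- log(tt[, 2])
  base <- ttheta_base(tt)
  s <- sample.int(H, 1)
  lr <- ttheta_logtarget(tt[s, , drop = FALSE], base[s], eta, sigma) -
    ttheta_logtarget(tt[idx, , drop = FALSE], base[idx], eta, sigma)
  acc <- log(runif(1)) < lr
  list(idx = if (acc) s else idx, proposed = s, log_ratio = as.numeric(lr),
       accepted = acc)
}

#' One reversible-jump update of a covariate-selection block
#'
#' Updates `(q, gamma, beta)` for one (parameter, covariate-group) block by
#' one of four moves chosen uniformly among those valid in the current
#' state: `add` (entering coefficient drawn from its prior), `delete`,
#' `swap` (coefficient of the entering column redrawn from the prior) and
#' `refresh` (conjugate Gibbs update of the coefficients at fixed `gamma`).
#' Acceptance combines the Gaussian random-effect density ratio, the
#' sub-model prior ratio and the proposal ratio; prior draws for entering
#' coefficients cancel against their prior densities, keeping the
#' trans-dimensional ratio simple.
#'
#' @param sel list(`gamma`, `beta`) for the block (`gamma` indexes `cols`).
#' @param cols integer indices of the group's columns in `X`.
#' @param X covariate design matrix (n x c).
#' @param resid0 length-n residuals of the parameter's modelling-scale
#'   values net of intercepts and the other groups' contributions.
#' @param sigma_l population residual sd for the parameter.
#' @param prior_sd coefficient prior sd for the group.
#' @param group `"continuous"`, `"binary"` or `"interaction"`.
#' @param loglik_weight set to 0 to run the block against a flat likelihood
#'   (prior-only chain), 1 for normal operation.
#' @param move force a specific move type (diagnostics only; default: drawn
#'   uniformly from the valid menu). Proposal probabilities in the
#'   acceptance ratio always refer to the uniform-menu kernel.
#' @return list(`sel`, `move`, `accepted`, `log_ratio`).
#' @export
rj_update_group <- function(sel, cols, X, resid0, sigma_l, prior_sd, group,
                            loglik_weight = 1, move = NULL) {
  c_g <- length(cols)
  if (c_g == 0) return(list(sel = sel, move = "none", accepted = FALSE))
  qmax <- if (group == "interaction") min(3, c_g) else c_g
  ll <- function(gamma, beta) {
    if (loglik_weight == 0) return(0)
    r <- resid0
    if (length(gamma))
      r <- r - as.numeric(X[, cols[gamma], drop = FALSE] %*% beta)
    loglik_weight * sum(dnorm(r, 0, sigma_l, log = TRUE))
  }
  lp <- function(q, gamma) model_prior_logpmf(group, q, gamma, c_g)
  menu_of <- function(q) {
    m <- character()
    if (q < qmax) m <- c(m, "add")
    if (q >= 1) m <- c(m, "delete", "refresh")
    if (q >= 1 && q < c_g) m <- c(m, "swap")
    m
  }
  q <- length(sel$gamma)
  menu <- menu_of(q)
  if (is.null(move)) move <- menu[sample.int(length(menu), 1)]
  stopifnot(move %in% menu)
  accepted <- FALSE
  log_ratio <- NA_real_
  if (move == "add") {
    free <- setdiff(seq_len(c_g), sel$gamma)
    j <- free[sample.int(length(free), 1)]
    bstar <- rnorm(1, 0, prior_sd)
    g2 <- c(sel$gamma, j); b2 <- c(sel$beta, bstar)
    lr <- ll(g2, b2) - ll(sel$gamma, sel$beta) +
      lp(q + 1, g2) - lp(q, sel$gamma) +
      log(1 / length(menu_of(q + 1))) + log(1 / (q + 1)) -
      log(1 / length(menu)) - log(1 / length(free))
    log_ratio <- lr
    if (is.finite(lr) && log(runif(1)) < lr) {
      sel <- list(gamma = g2, beta = b2); accepted <- TRUE
    }
  } else if (move == "delete") {
    d <- sample.int(q, 1)
    g2 <- sel$gamma[-d]; b2 <- sel$beta[-d]
    lr <- ll(g2, b2) - ll(sel$gamma, sel$beta) +
      lp(q - 1, g2) - lp(q, sel$gamma) +
      log(1 / length(menu_of(q - 1))) + log(1 / (c_g - q + 1)) -
      log(1 / length(menu)) - log(1 / q)
    log_ratio <- lr
    if (is.finite(lr) && log(runif(1)) < lr) {
      sel <- list(gamma = g2, beta = b2); accepted <- TRUE
    }
  } else if (move == "swap") {
    d <- sample.int(q, 1)
    free <- setdiff(seq_len(c_g), sel$gamma)
    j <- free[sample.int(length(free), 1)]
    bstar <- rnorm(1, 0, prior_sd)
    g2 <- sel$gamma; g2[d] <- j
    b2 <- sel$beta; b2[d] <- bstar
    lr <- ll(g2, b2) - ll(sel$gamma, sel$beta)   # prior & proposal symmetric
    log_ratio <- lr
    if (is.finite(lr) && log(runif(1)) < lr) {
      sel <- list(gamma = g2, beta = b2); accepted <- TRUE
    }
  } else if (move == "refresh") {
    # conjugate Gibbs for beta | gamma: always accepted
    W <- X[, cols[sel$gamma], drop = FALSE]
    if (loglik_weight == 0) {
      sel$beta <- rnorm(q, 0, prior_sd)
    } else {
      A <- crossprod(W) / sigma_l^2 + diag(q) / prior_sd^2
      bvec <- crossprod(W, resid0) / sigma_l^2
      U <- chol(A)
      m <- backsolve(U, backsolve(U, bvec, transpose = TRUE))
      sel$beta <- as.numeric(m + backsolve(U, rnorm(q)))
    }
    accepted <- TRUE
  }
  list(sel = sel, move = move, accepted = accepted, log_ratio = log_ratio)
}

# ---------------------------------------------------------------------------
# the full stage-2 sampler
# ---------------------------------------------------------------------------

empty_sel <- function() {
  lapply(1:4, function(l)
    list(continuous = list(gamma = integer(), beta = numeric()),
         binary = list(gamma = integer(), beta = numeric()),
         interaction = list(gamma = integer(), beta = numeric())))
}

# selection state -> covariate contribution (n) for parameter l, with gamma
# stored group-locally (indices into the group's columns)
sel_contribution <- function(sel_l, gcols, X) {
  out <- numeric(nrow(X))
  for (g in names(sel_l)) {
    gm <- sel_l[[g]]$gamma
    if (length(gm))
      out <- out + as.numeric(X[, gcols[[g]][gm], drop = FALSE] %*%
                                sel_l[[g]]$beta)
  }
  out
}

#' Fit the hierarchical population model (stage 2)
#'
#' Systematic-scan MCMC over the full hierarchical model, reusing the
#' stage-1 store: conjugate Gibbs for all intercepts, slice sampling for all
#' sds, resampling Metropolis-Hastings for every profile's kinetic
#' parameters (the stored stage-1 draws are the proposals, so the ODE
#' likelihood is never evaluated), and — when covariate selection is on —
#' one reversible-jump update of each of the 12 (parameter x group) blocks
#' per sweep. Deterministic given `seed`.
#'
#' @param store a `stage1_store` covering all included profiles.
#' @param dataset a [pk_dataset()]; profiles flagged in the store are
#'   dropped.
#' @param spec a [model_spec()].
#' @param config a [stage2_config()].
#' @param seed integer seed.
#' @return object of class `stage2_fit` with thinned draws of all
#'   population parameters, per-draw covariate-selection states, and
#'   acceptance bookkeeping.
#' @export
run_stage2 <- function(store, dataset, spec, config = stage2_config(),
                       seed = 1) {
  set.seed(seed)
  ids <- intersect(names(included_profiles(dataset)), names(store$entries))
  ids <- setdiff(ids, names(store$excluded))
  if (!length(ids)) stop("no profiles common to dataset and store")
  profs <- dataset$profiles[ids]
  struct <- hier_index(profs)
  n <- length(ids)
  design <- if (spec$covariates) subset_design(dataset$design, ids) else NULL
  if (spec$covariates && is.null(design))
    stop("covariate selection requested but dataset has no design")
  gcols <- if (spec$covariates) group_columns(design) else NULL
  delta_beta <- spec$delta_beta
  if (spec$covariates && is.null(delta_beta))
    delta_beta <- delta_beta_from_store(store)

  # flatten the stored draws for vectorized resampling
  tt_list <- lapply(store$entries[ids], function(e) {
    tt <- e$draws[, 1:4, drop = FALSE]
    tt[, 1] <- log(tt[, 1]); tt[, 2] <- log(tt[, 2])
    tt
  })
  H <- vapply(tt_list, nrow, integer(1))
  offset <- cumsum(c(0, H[-n]))
  tt_flat <- do.call(rbind, tt_list)
  base_flat <- ttheta_base(tt_flat)

  # initial state: stage-1 medians
  med <- t(vapply(tt_list, function(tt) apply(tt, 2, median), numeric(4)))
  idx_cur <- vapply(seq_len(n), function(i) {
    tt <- tt_list[[i]]
    sds <- apply(tt, 2, sd)
    sds[!is.finite(sds) | sds < 1e-9] <- 1
    which.min(colSums(((t(tt) - med[i, ]) / sds)^2))
  }, integer(1))
  tt_cur <- tt_flat[offset + idx_cur, , drop = FALSE]
  base_cur <- base_flat[offset + idx_cur]

  N <- struct$n_women
  V <- if (spec$level == "threeV") struct$n_visits else
    if (spec$level == "threeM") struct$n_meals else 0
  unit_of <- switch(spec$level, threeV = struct$visit, threeM = struct$meal,
                    NULL)
  woman_of_unit <- switch(spec$level, threeV = struct$woman_of_visit,
                          threeM = struct$woman_of_meal, NULL)
  phi <- colMeans(med)
  psi <- if (spec$level != "one")
    apply(med, 2, function(x) tapply(x, struct$woman, mean)) else NULL
  if (!is.null(psi)) psi <- matrix(psi, nrow = N)
  chi <- if (V > 0)
    matrix(apply(med, 2, function(x) tapply(x, unit_of, mean)), nrow = V)
  else NULL
  sigma_theta <- pmax(apply(med, 2, sd), 0.05)
  sigma_psi <- if (!is.null(psi)) pmax(apply(psi, 2, sd), 0.05) else rep(NA, 4)
  sigma_chi <- if (V > 0) rep(0.5, 4) * sigma_theta + 0.02 else rep(NA, 4)
  sel <- empty_sel()
  prior_sd_g <- if (spec$covariates)
    vapply(1:4, function(l) c(
      continuous = coefficient_prior_sd(delta_beta[l], "continuous"),
      binary = coefficient_prior_sd(delta_beta[l], "binary"),
      interaction = coefficient_prior_sd(delta_beta[l], "interaction")),
      numeric(3)) else NULL   # 3 x 4 matrix

  S <- (config$iterations - config$burn_in) %/% config$thin
  cnames <- if (spec$covariates) colnames(design$X) else NULL
  out <- list(
    phi = matrix(NA_real_, S, 4), sigma_theta = matrix(NA_real_, S, 4),
    sigma_psi = matrix(NA_real_, S, 4), sigma_chi = matrix(NA_real_, S, 4),
    psi = if (config$store_effects && !is.null(psi))
      array(NA_real_, c(S, N, 4)) else NULL,
    chi = if (config$store_effects && V > 0)
      array(NA_real_, c(S, V, 4)) else NULL,
    inclusion = if (spec$covariates)
      array(FALSE, c(S, 4, ncol(design$X)),
            dimnames = list(NULL, PARAM_NAMES[1:4], cnames)) else NULL,
    beta = if (spec$covariates)
      array(NA_real_, c(S, 4, ncol(design$X)),
            dimnames = list(NULL, PARAM_NAMES[1:4], cnames)) else NULL,
    theta_idx = matrix(NA_integer_, S, n, dimnames = list(NULL, ids)))
  acc_resample <- 0; rj_stats <- c(attempt = 0, accept = 0)

  keep <- 0
  for (it in seq_len(config$iterations)) {
    covc <- if (spec$covariates)
      vapply(1:4, function(l) sel_contribution(sel[[l]], gcols, design$X),
             numeric(n)) else matrix(0, n, 4)
    covc <- matrix(covc, n, 4)
    r <- tt_cur - covc   # residuals net of covariates, per parameter

    # -- intercepts (top-down Gibbs) --
    for (l in 1:4) {
      if (spec$level == "one") {
        phi[l] <- gibbs_update_intercept(0, spec$phi_prior_sd[l],
                                         sum(r[, l]), n, sigma_theta[l])
      } else if (spec$level == "two") {
        phi[l] <- gibbs_update_intercept(0, spec$phi_prior_sd[l],
                                         sum(psi[, l]), N, sigma_psi[l])
        sums <- tapply(r[, l], struct$woman, sum)
        cnts <- tabulate(struct$woman, N)
        psi[, l] <- gibbs_update_intercept(phi[l], sigma_psi[l],
                                           as.numeric(sums), cnts,
                                           sigma_theta[l])
      } else {
        phi[l] <- gibbs_update_intercept(0, spec$phi_prior_sd[l],
                                         sum(psi[, l]), N, sigma_psi[l])
        csums <- tapply(chi[, l], woman_of_unit, sum)
        ccnts <- tabulate(woman_of_unit, N)
        psi[, l] <- gibbs_update_intercept(phi[l], sigma_psi[l],
                                           as.numeric(csums), ccnts,
                                           sigma_chi[l])
        sums <- tapply(r[, l], unit_of, sum)
        cnts <- tabulate(unit_of, V)
        chi[, l] <- gibbs_update_intercept(psi[woman_of_unit, l],
                                           sigma_chi[l], as.numeric(sums),
                                           cnts, sigma_theta[l])
      }
    }

    # -- variance components (slice) --
    intercept_prof <- switch(spec$level,
      one = matrix(phi, n, 4, byrow = TRUE),
      two = psi[struct$woman, , drop = FALSE],
      matrix(chi[unit_of, ], n, 4))
    for (l in 1:4) {
      d <- r[, l] - intercept_prof[, l]
      sigma_theta[l] <- slice_update_sd(sigma_theta[l], sum(d^2), n,
                                        spec$sd_upper, config$slice_w)
      if (spec$level == "two") {
        dp <- psi[, l] - phi[l]
        sigma_psi[l] <- slice_update_sd(sigma_psi[l], sum(dp^2), N,
                                        spec$sd_upper, config$slice_w)
      } else if (spec$level %in% c("threeV", "threeM")) {
        dp <- psi[, l] - phi[l]
        sigma_psi[l] <- slice_update_sd(sigma_psi[l], sum(dp^2), N,
                                        spec$sd_upper, config$slice_w)
        dc <- chi[, l] - psi[woman_of_unit, l]
        sigma_chi[l] <- slice_update_sd(sigma_chi[l], sum(dc^2), V,
                                        spec$sd_upper, config$slice_w)
      }
    }

    # -- profile parameters: resampling MH (no likelihood, no ODE) --
    eta_prof <- intercept_prof + covc
    s_prop <- offset + (floor(runif(n) * H) + 1L)
    tt_prop <- tt_flat[s_prop, , drop = FALSE]
    lr <- base_flat[s_prop] - base_cur
    for (l in 1:4)
      lr <- lr + dnorm(tt_prop[, l], eta_prof[, l], sigma_theta[l],
                       log = TRUE) -
        dnorm(tt_cur[, l], eta_prof[, l], sigma_theta[l], log = TRUE)
    acc <- log(runif(n)) < lr
    idx_cur[acc] <- s_prop[acc] - offset[acc]
    tt_cur[acc, ] <- tt_prop[acc, , drop = FALSE]
    base_cur[acc] <- base_flat[s_prop][acc]
    acc_resample <- acc_resample + mean(acc)

    # -- reversible-jump covariate selection --
    if (spec$covariates) {
      for (l in 1:4) {
        for (g in c("continuous", "binary", "interaction")) {
          if (!length(gcols[[g]])) next
          other <- sel_contribution(sel[[l]], gcols, design$X) -
            {gm <- sel[[l]][[g]]$gamma
             if (length(gm))
               as.numeric(design$X[, gcols[[g]][gm], drop = FALSE] %*%
                            sel[[l]][[g]]$beta) else 0}
          resid0 <- tt_cur[, l] - intercept_prof[, l] - other
          upd <- rj_update_group(sel[[l]][[g]], gcols[[g]], design$X,
                                 resid0, sigma_theta[l],
                                 prior_sd_g[g, l], g)
          sel[[l]][[g]] <- upd$sel
          rj_stats["attempt"] <- rj_stats["attempt"] + 1
          rj_stats["accept"] <- rj_stats["accept"] + upd$accepted
        }
      }
    }

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0 &&
        keep < S) {
      keep <- keep + 1
      out$phi[keep, ] <- phi
      out$sigma_theta[keep, ] <- sigma_theta
      out$sigma_psi[keep, ] <- sigma_psi
      out$sigma_chi[keep, ] <- sigma_chi
      if (!is.null(out$psi)) out$psi[keep, , ] <- psi
      if (!is.null(out$chi)) out$chi[keep, , ] <- chi
      if (spec$covariates) {
        for (l in 1:4) for (g in c("continuous", "binary", "interaction")) {
          gm <- sel[[l]][[g]]$gamma
          if (length(gm)) {
            cidx <- gcols[[g]][gm]
            out$inclusion[keep, l, cidx] <- TRUE
            out$beta[keep, l, cidx] <- sel[[l]][[g]]$beta
          }
        }
      }
      out$theta_idx[keep, ] <- idx_cur
    }
  }

  structure(list(
    draws = out, spec = spec, config = config, seed = seed,
    profile_ids = ids, struct = struct,
    design = design, delta_beta = delta_beta,
    acceptance = list(resample = acc_resample / config$iterations,
                      rj = unname(rj_stats["accept"] /
                                    max(rj_stats["attempt"], 1)))),
    class = "stage2_fit")
}

#' @export
print.stage2_fit <- function(x, ...) {
  cat("<stage2_fit>", x$spec$level, "level model,",
      if (x$spec$covariates) "with" else "without", "covariates;",
      nrow(x$draws$phi), "stored draws over", length(x$profile_ids),
      "profiles\n")
  cat("  resampling acceptance:", round(x$acceptance$resample, 3), "\n")
  invisible(x)
}

#' Run several stage-2 chains and assess convergence
#'
#' @param store,dataset,spec,config as in [run_stage2()].
#' @param seed master seed; chain c uses a derived seed.
#' @param n_chains number of chains.
#' @return list(`fits`, `bgr`): per-chain fits and the BGR statistic over
#'   the global intercepts and residual sds.
#' @export
run_stage2_chains <- function(store, dataset, spec,
                              config = stage2_config(), seed = 1,
                              n_chains = 2) {
  fits <- lapply(seq_len(n_chains), function(ch)
    run_stage2(store, dataset, spec, config, seed = profile_seed(seed, ch)))
  chains <- lapply(fits, function(f) {
    m <- cbind(f$draws$phi, f$draws$sigma_theta)
    colnames(m) <- c(paste0("phi_", 1:4), paste0("sigma_theta_", 1:4))
    m
  })
  list(fits = fits, bgr = if (n_chains >= 2) bgr_diagnostic(chains) else NULL)
}

# ---------------------------------------------------------------------------
# summaries
# ---------------------------------------------------------------------------

#' Marginal posterior inclusion probabilities
#'
#' Fraction of post-burn-in draws in which each design column is selected
#' for each kinetic parameter. An inclusion probability above 0.5 is
#' conventionally read as a notable association.
#'
#' @param fit a `stage2_fit` from a run with covariate selection.
#' @return 4 x c matrix of probabilities in `[0, 1]`.
#' @export
inclusion_probabilities <- function(fit) {
  if (is.null(fit$draws$inclusion))
    stop("fit was run without covariate selection")
  apply(fit$draws$inclusion, c(2, 3), mean)
}

#' Posterior variance decomposition
#'
#' Apportions each kinetic parameter's variability among the hierarchy
#' levels present in the model (between-woman, between-visit or
#' between-mealtime, residual). Proportions are computed per draw (so they
#' sum to 1 in every draw) and averaged.
#'
#' @param fit a `stage2_fit`.
#' @return list with `variances` (posterior means of each sd^2 component)
#'   and `proportions` (posterior mean shares), both parameters x
#'   components.
#' @export
variance_decomposition <- function(fit) {
  lv <- fit$spec$level
  comp <- switch(lv,
    one = list(residual = fit$draws$sigma_theta^2),
    two = list(woman = fit$draws$sigma_psi^2,
               residual = fit$draws$sigma_theta^2),
    threeV = list(woman = fit$draws$sigma_psi^2,
                  visit = fit$draws$sigma_chi^2,
                  residual = fit$draws$sigma_theta^2),
    threeM = list(woman = fit$draws$sigma_psi^2,
                  mealtime = fit$draws$sigma_chi^2,
                  residual = fit$draws$sigma_theta^2))
  tot <- Reduce(`+`, comp)
  vars <- vapply(comp, colMeans, numeric(4))
  props <- vapply(comp, function(v) colMeans(v / tot), numeric(4))
  rownames(vars) <- rownames(props) <- PARAM_NAMES[1:4]
  list(variances = vars, proportions = props)
}

#' Conditional covariate-effect summaries and typical parameters
#'
#' Coefficient summaries are conditional on inclusion: the posterior mean
#' and sd of each beta over the draws in which its column is selected
#' (columns never selected are reported as `NA`, not zero). For t_max and
#' MCR the effect is also expressed as a percentage change per unit,
#' `100 (exp(beta) - 1)`. Typical parameter values per study-mealtime cell
#' set all continuous and binary covariates to zero: the cell's value is
#' `phi_l` plus the cell indicator's coefficient when selected, mapped
#' through `exp` for the log-scale parameters.
#'
#' @param fit a `stage2_fit` with covariate selection.
#' @return list with data frames `effects` (per parameter x column) and
#'   `typical` (per parameter x interaction cell).
#' @export
conditional_effect_summaries <- function(fit) {
  if (is.null(fit$draws$beta))
    stop("fit was run without covariate selection")
  cn <- dimnames(fit$draws$beta)[[3]]
  eff <- do.call(rbind, lapply(1:4, function(l) {
    do.call(rbind, lapply(seq_along(cn), function(j) {
      b <- fit$draws$beta[, l, j]
      inc <- fit$draws$inclusion[, l, j]
      b <- b[inc]
      pct <- if (l <= 2 && length(b)) 100 * (exp(b) - 1) else NA_real_
      data.frame(parameter = PARAM_NAMES[l], covariate = cn[j],
                 p_include = mean(inc),
                 mean = if (length(b)) mean(b) else NA_real_,
                 sd = if (length(b) > 1) sd(b) else NA_real_,
                 pct_mean = if (l <= 2 && length(b)) mean(pct) else NA_real_,
                 pct_sd = if (l <= 2 && length(b) > 1) sd(pct) else NA_real_)
    }))
  }))
  cells <- grep("^study[12]_", cn, value = TRUE)
  typical <- do.call(rbind, lapply(1:4, function(l) {
    do.call(rbind, lapply(cells, function(cell) {
      j <- match(cell, cn)
      b <- ifelse(fit$draws$inclusion[, l, j], fit$draws$beta[, l, j], 0)
      v <- fit$draws$phi[, l] + b
      if (l <= 2) v <- exp(v)
      data.frame(parameter = PARAM_NAMES[l], cell = cell, mean = mean(v),
                 sd = sd(v))
    }))
  }))
  list(effects = eff, typical = typical)
}
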