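#' Direct single-stage fit of the one-level hierarchical model
#'
#' Reference sampler that fits the joint hierarchical model in one stage,
#' evaluating the ODE likelihood at every profile-parameter update:
#' componentwise adaptive random-walk Metropolis for each profile's
#' (theta, kappa, lambda) under the current population prior, conjugate
#' Gibbs for the global intercepts and slice sampling for the residual sds.
#' Supports the one-level model without covariates; its purpose is to
#' validate that the two-stage scheme targets the same joint posterior,
#' so it is deliberately simple (and slow).
#'
#' @param dataset a [pk_dataset()].
#' @param iterations,burn_in,thin chain settings (sweeps).
#' @param seed integer seed.
#' @param phi_prior_sd,sd_upper prior constants, as in [model_spec()].
#' @return list with matrices `phi` (S x 4) and `sigma_theta` (S x 4) of
#'   thinned post-burn-in draws, plus `theta` draws per profile.
#' @export
run_joint_mcmc <- function(dataset, iterations = 6000, burn_in = 2000,
                           thin = 2, seed = 1,
                           phi_prior_sd = c(100, 100, 1000, 1000),
                           sd_upper = 100) {
  set.seed(seed)
  profs <- included_profiles(dataset)
  n <- length(profs)
  pw <- lapply(profs, function(p) dosing_breaks(p$dosing))

  # initial states: crude per-profile values
  state <- t(vapply(profs, function(p)
    c(60, 0.03, 0, median(p$conc), 5, 0.1), numeric(6)))
  lsteps <- matrix(log(c(0.1, 0.2, 0.05, 2, 0.3, 0.3)), n, 6, byrow = TRUE)
  ttheta <- function(st) cbind(log(st[, 1]), log(st[, 2]), st[, 3], st[, 4])
  tt <- ttheta(state)
  phi <- colMeans(tt)
  sigma_theta <- pmax(apply(tt, 2, sd), 0.1)

  S <- (iterations - burn_in) %/% thin
  out_phi <- matrix(NA_real_, S, 4)
  out_sig <- matrix(NA_real_, S, 4)
  out_theta <- array(NA_real_, c(S, n, 4))
  acc_batch <- matrix(0, n, 6); batch <- 0
  keep <- 0
  for (it in seq_len(iterations)) {
    for (i in seq_len(n)) {
      p <- profs[[i]]
      res <- profile_sweep_cpp(p$conc, p$times, pw[[i]]$breaks,
                               pw[[i]]$rates, p$wt, p$t_end,
                               p$unit_conversion, state[i, ],
                               exp(lsteps[i, ]), phi, sigma_theta,
                               1e-6, 1e-6)
      state[i, ] <- res$state
      acc_batch[i, ] <- acc_batch[i, ] + res$accept
    }
    if (it <= burn_in && it %% 50 == 0) {
      batch <- batch + 1
      delta <- min(0.05, 1 / sqrt(batch))
      lsteps <- lsteps + ifelse(acc_batch / 50 > 0.44, delta, -delta)
      acc_batch[] <- 0
    }
    tt <- ttheta(state)
    for (l in 1:4) {
      phi[l] <- gibbs_update_intercept(0, phi_prior_sd[l], sum(tt[, l]), n,
                                       sigma_theta[l])
      d <- tt[, l] - phi[l]
      sigma_theta[l] <- slice_update_sd(sigma_theta[l], sum(d^2), n,
                                        sd_upper)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0 && keep < S) {
      keep <- keep + 1
      out_phi[keep, ] <- phi
      out_sig[keep, ] <- sigma_theta
      out_theta[keep, , ] <- state[, 1:4]
    }
  }
  list(phi = out_phi, sigma_theta = out_sig, theta = out_theta,
       profile_ids = names(profs))
}
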