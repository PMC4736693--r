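#' Stage-1 prior specification
#'
#' Flat priors for the per-profile fit: `t_max ~ U(5, 500)` min and
#' `MCR ~ U(0, 0.25)` l/kg/min span the physiologically plausible ranges;
#' `a, b ~ N(0, 100^2)`; the residual nuisance parameters keep their
#' `kappa ~ U(0, 100)`, `lam ~ U(0, 1)` priors. These constants are fixed:
#' they define the stage-1 target whose draws stage 2 reuses, so the
#' stage-1-prior correction in the stage-2 acceptance ratio depends on them.
#' @return named list of prior bounds/sds.
#' @export
stage1_prior <- function() {
  list(t_max = c(5, 500), mcr = c(0, 0.25), a_sd = 100, b_sd = 100,
       kappa = c(0, 100), lam = c(0, 1))
}

#' Stage-1 run configuration
#'
#' Defaults are a scaled-down working configuration (production analyses
#' would use far longer chains with heavier thinning).
#'
#' @param burn_in adaptation/burn-in iterations (discarded).
#' @param iterations post-burn-in iterations per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param n_chains number of chains (>= 2 enables the BGR diagnostic).
#' @export
stage1_config <- function(burn_in = 5000, iterations = 20000, thin = 20,
                          n_chains = 2) {
  stopifnot(burn_in >= 0, iterations > 0, thin >= 1, n_chains >= 1)
  list(burn_in = burn_in, iterations = iterations, thin = thin,
       n_chains = n_chains)
}

PARAM_NAMES <- c("t_max", "mcr", "a", "b", "kappa", "lam")

stage1_inits <- function(profile, chain) {
  ymed <- median(profile$conc)
  if (chain == 1) {
    c(60, 0.03, 0, ymed, 5, 0.1)
  } else {
    c(runif(1, 10, 400), runif(1, 0.005, 0.2), rnorm(1, 0, 2),
      ymed + rnorm(1, 0, 30), runif(1, 1, 30), runif(1, 0.02, 0.5))
  }
}

#' Fit one profile by adaptive MCMC under flat priors
#'
#' Componentwise random-walk Metropolis on transformed scales (log t_max,
#' logit MCR/0.25, identity a and b, logit kappa/100, logit lam), with
#' per-component step sizes adapted toward a 0.44 acceptance rate during
#' burn-in only, so the post-burn-in kernel preserves detailed balance.
#' Requires at least 6 observations (more data points than parameters).
#'
#' @param profile a [pk_profile()].
#' @param config a [stage1_config()].
#' @param seed integer seed.
#' @param fix_lambda fix the multiplicative residual coefficient at 0
#'   (additive-error model); used mainly for validation against grid
#'   posteriors.
#' @return list with `draws` (H x 6 matrix over all chains, columns
#'   `r PARAM_NAMES`), `chains` (per-chain thinned draws, for diagnostics),
#'   `bgr` (per-parameter potential scale reduction, `NA` for a single
#'   chain), `acceptance`, `flag`/`flag_reason` (unfittable-profile marker)
#'   and `meta`.
#' @export
run_stage1 <- function(profile, config = stage1_config(), seed = 1,
                       fix_lambda = FALSE) {
  stopifnot(inherits(profile, "pk_profile"))
  if (length(profile$times) < 6)
    stop("profile ", profile$profile_id,
         " has fewer than 6 observations; cannot fit 6 parameters")
  pw <- dosing_breaks(profile$dosing)
  n_iter <- config$burn_in + config$iterations
  chains <- vector("list", config$n_chains)
  acc <- NULL
  flag <- FALSE; flag_reason <- NA_character_
  for (ch in seq_len(config$n_chains)) {
    set.seed(profile_seed(seed, ch))
    init <- stage1_inits(profile, ch)
    if (fix_lambda) init[6] <- 1e-8   # additive-error model
    res <- tryCatch(
      profile_chain_cpp(profile$conc, profile$times, pw$breaks, pw$rates,
                        profile$wt, profile$t_end, profile$unit_conversion,
                        init, n_iter, config$burn_in, config$thin,
                        pop = FALSE, numeric(4), numeric(4),
                        fix_lam = fix_lambda, rtol = 1e-6, atol = 1e-6),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(list(draws = NULL, chains = NULL, bgr = NULL, acceptance = NULL,
                  flag = TRUE,
                  flag_reason = paste0("integration failure: ",
                                       conditionMessage(res)),
                  meta = list(profile_id = profile$profile_id, seed = seed,
                              config = config, prior = stage1_prior())))
    }
    colnames(res$draws) <- PARAM_NAMES
    chains[[ch]] <- res$draws
    acc <- res$acceptance
  }
  draws <- do.call(rbind, chains)
  bgr <- if (config$n_chains >= 2) bgr_diagnostic(chains) else
    setNames(rep(NA_real_, 6), PARAM_NAMES)
  # exclusion proxies for "unable to fit": poor convergence, or posterior
  # mass piled within 1% of a kinetic-parameter prior bound
  if (config$n_chains >= 2 && any(bgr[c("t_max", "mcr")] > 1.1,
                                  na.rm = TRUE)) {
    flag <- TRUE; flag_reason <- "BGR > 1.1 on a kinetic parameter"
  }
  pr <- stage1_prior()
  eps_t <- 0.01 * diff(pr$t_max); eps_m <- 0.01 * diff(pr$mcr)
  near <- max(mean(draws[, "t_max"] < pr$t_max[1] + eps_t |
                     draws[, "t_max"] > pr$t_max[2] - eps_t),
              mean(draws[, "mcr"] > pr$mcr[2] - eps_m))
  if (!flag && near > 0.05) {
    flag <- TRUE
    flag_reason <- "posterior mass concentrated at a stage-1 prior bound"
  }
  list(draws = draws, chains = chains, bgr = bgr, acceptance = acc,
       flag = flag, flag_reason = flag_reason,
       meta = list(profile_id = profile$profile_id, seed = seed,
                   config = config, prior = stage1_prior(),
                   fix_lambda = fix_lambda))
}

#' Fit all included profiles and assemble the stage-1 store
#'
#' Runs [run_stage1()] per included profile with a per-profile seed stream
#' and records flagged (unfittable) profiles as excluded, mirroring the
#' practice of dropping profiles the profile-level model cannot fit.
#'
#' @param dataset a [pk_dataset()].
#' @param config a [stage1_config()].
#' @param seed integer master seed.
#' @return object of class `stage1_store`: `entries` (per profile id),
#'   `excluded` (named reasons), `config`, `seed`.
#' @export
run_stage1_all <- function(dataset, config = stage1_config(), seed = 1) {
  profs <- included_profiles(dataset)
  entries <- list(); excluded <- character()
  for (idx in seq_along(profs)) {
    p <- profs[[idx]]
    e <- run_stage1(p, config, seed = profile_seed(seed, 1000 + idx))
    if (e$flag) excluded[p$profile_id] <- e$flag_reason
    if (!is.null(e$draws)) entries[[p$profile_id]] <- e
  }
  structure(list(entries = entries, excluded = excluded, config = config,
                 seed = seed),
            class = "stage1_store")
}

#' @export
print.stage1_store <- function(x, ...) {
  H <- if (length(x$entries)) nrow(x$entries[[1]]$draws) else 0
  cat("<stage1_store>", length(x$entries), "profiles,", H,
      "stored draws each;", length(x$excluded), "flagged\n")
  invisible(x)
}

#' Brooks-Gelman-Rubin potential scale reduction
#'
#' Classic PSRF from two or more equal-length chains: with within-chain
#' variance W and between-chain variance B (of the chain means, times chain
#' length n), the pooled variance estimate is `(n-1)/n W + B/n` and the
#' statistic is the square root of its ratio to W. Values near 1 indicate
#' convergence; identical chains give a value at most 1. The statistic is
#' invariant to a common affine transformation of all chains.
#'
#' @param chains list of >= 2 numeric matrices (iterations x parameters) of
#'   equal dimension, or list of equal-length vectors.
#' @return named per-parameter statistic.
#' @export
bgr_diagnostic <- function(chains) {
  stopifnot(length(chains) >= 2)
  chains <- lapply(chains, function(x) if (is.matrix(x)) x else cbind(x))
  n <- nrow(chains[[1]]); p <- ncol(chains[[1]])
  stopifnot(n >= 10, all(vapply(chains, nrow, 1L) == n),
            all(vapply(chains, ncol, 1L) == p))
  out <- vapply(seq_len(p), function(j) {
    xs <- lapply(chains, function(c) c[, j])
    W <- mean(vapply(xs, var, numeric(1)))
    B_n <- var(vapply(xs, mean, numeric(1)))   # = B/n
    if (W == 0) return(1)
    sqrt((n - 1) / n + B_n / W)
  }, numeric(1))
  names(out) <- colnames(chains[[1]])
  out
}

#' Stage-1 fit diagnostics for one profile
#'
#' Posterior-median fit curve, a 95% posterior-predictive band, and
#' standardized residuals `(y - mu_hat)/sigma_hat` computed at the posterior
#' medians, tabulated against time and against the predicted concentration
#' (plot-ready).
#'
#' @param profile a [pk_profile()].
#' @param draws H x 6 stage-1 draw matrix (columns as in [run_stage1()]).
#' @param n_band number of draws subsampled for the predictive band.
#' @return data frame with columns `time`, `observed`, `predicted`, `lo`,
#'   `hi`, `resid_std`.
#' @export
fit_diagnostics <- function(profile, draws, n_band = 300) {
  stopifnot(nrow(draws) >= 1)
  med <- apply(draws, 2, median)
  params <- kinetic_params(med["t_max"], med["mcr"], med["a"], med["b"])
  ctx <- profile_ctx(profile)
  sol <- integrate_compartments(profile$dosing, params$t_max, profile$times)
  mu_hat <- predicted_concentration(params, ctx, profile$times, sol$Q2)
  sd_hat <- sqrt(med["kappa"]^2 + med["lam"]^2 * mu_hat^2)
  take <- draws[seq(1, nrow(draws),
                    length.out = min(n_band, nrow(draws))), , drop = FALSE]
  yrep <- apply(take, 1, function(d) {
    pr <- kinetic_params(d["t_max"], d["mcr"], d["a"], d["b"])
    s <- integrate_compartments(profile$dosing, d["t_max"], profile$times)
    mu <- predicted_concentration(pr, ctx, profile$times, s$Q2)
    rnorm(length(mu), mu, sqrt(d["kappa"]^2 + d["lam"]^2 * mu^2))
  })
  data.frame(time = profile$times, observed = profile$conc,
             predicted = mu_hat,
             lo = apply(yrep, 1, quantile, 0.025),
             hi = apply(yrep, 1, quantile, 0.975),
             resid_std = (profile$conc - mu_hat) / sd_hat)
}

#' Write / read a stage-1 store as delimited text
#'
#' `draws.tsv` holds all stored draws (one row per draw, keyed by profile
#' id); `store_meta.tsv` holds the run configuration, seed and flags —
#' together sufficient to regenerate the store.
#' @param store a `stage1_store`.
#' @param dir directory path.
#' @export
write_stage1_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(store$entries), function(id) {
    d <- as.data.frame(store$entries[[id]]$draws)
    cbind(profile_id = id, draw = seq_len(nrow(d)), d)
  })
  write.table(do.call(rbind, rows), file.path(dir, "draws.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  meta <- data.frame(
    format_version = 1, seed = store$seed,
    burn_in = store$config$burn_in, iterations = store$config$iterations,
    thin = store$config$thin, n_chains = store$config$n_chains)
  write.table(meta, file.path(dir, "store_meta.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (length(store$excluded))
    write.table(data.frame(profile_id = names(store$excluded),
                           reason = unname(store$excluded)),
                file.path(dir, "store_excluded.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_stage1_store
#' @export
read_stage1_store <- function(dir) {
  dr <- read.delim(file.path(dir, "draws.tsv"))
  meta <- read.delim(file.path(dir, "store_meta.tsv"))
  entries <- lapply(split(dr, dr$profile_id), function(d) {
    m <- as.matrix(d[PARAM_NAMES])
    rownames(m) <- NULL
    list(draws = m, chains = NULL, bgr = NULL, acceptance = NULL,
         flag = FALSE, flag_reason = NA_character_,
         meta = list(profile_id = d$profile_id[1], seed = meta$seed,
                     prior = stage1_prior()))
  })
  entries <- entries[unique(dr$profile_id)]
  excluded <- character()
  f <- file.path(dir, "store_excluded.tsv")
  if (file.exists(f)) {
    ex <- read.delim(f); excluded <- setNames(ex$reason, ex$profile_id)
  }
  structure(list(entries = entries, excluded = excluded,
                 config = stage1_config(meta$burn_in, meta$iterations,
                                        meta$thin, meta$n_chains),
                 seed = meta$seed),
            class = "stage1_store")
}
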