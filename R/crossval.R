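#' Predictive-prior draws for an omitted profile
#'
#' Simulates the omitted profile's kinetic parameters from the population
#' model averaged over a stage-2 posterior fitted without that profile: for
#' each retained draw of the population parameters, the profile's linear
#' predictor is assembled from its covariate row and hierarchy position, and
#' a parameter vector is drawn from the population distribution. When the
#' fit identifies the omitted profile's woman (or visit/meal) intercept
#' through sibling profiles, the fitted intercept draw is used; otherwise a
#' fresh intercept is drawn from its population distribution.
#'
#' @param fit a `stage2_fit` from a run with this profile excluded.
#' @param dataset the full [pk_dataset()] (supplies the omitted profile's
#'   covariate row on the full-data standardization, and its hierarchy
#'   position).
#' @param profile_id the omitted profile.
#' @return S x 4 matrix of predictive draws on the natural scale (t_max and
#'   MCR strictly positive).
#' @export
predictive_prior_draws <- function(fit, dataset, profile_id) {
  prof <- dataset$profiles[[profile_id]]
  if (is.null(prof)) stop("unknown profile: ", profile_id)
  if (profile_id %in% fit$profile_ids)
    stop("profile ", profile_id, " was not excluded from the fit")
  d <- fit$draws
  S <- nrow(d$phi)
  spec <- fit$spec
  st <- fit$struct
  wkey <- as.character(prof$woman)
  vkey <- paste(prof$woman, prof$visit, sep = ":")
  mkey <- paste(prof$woman, prof$meal, sep = ":")
  wi <- match(wkey, st$woman_levels)
  ui <- switch(spec$level, threeV = match(vkey, st$visit_levels),
               threeM = match(mkey, st$meal_levels), NA_integer_)

  wrow <- if (spec$covariates)
    dataset$design$X[match(profile_id, dataset$design$profile_id), ]
  else NULL

  out <- matrix(NA_real_, S, 4,
                dimnames = list(NULL, PARAM_NAMES[1:4]))
  for (l in 1:4) {
    if (spec$level == "one") {
      intercept <- d$phi[, l]
    } else {
      psi_l <- if (!is.na(wi) && !is.null(d$psi)) d$psi[, wi, l]
      else rnorm(S, d$phi[, l], d$sigma_psi[, l])
      if (spec$level == "two") {
        intercept <- psi_l
      } else {
        intercept <- if (!is.na(ui) && !is.null(d$chi)) d$chi[, ui, l]
        else rnorm(S, psi_l, d$sigma_chi[, l])
      }
    }
    covterm <- 0
    if (spec$covariates) {
      b <- d$beta[, l, , drop = FALSE][, 1, ]
      inc <- d$inclusion[, l, , drop = FALSE][, 1, ]
      covterm <- as.numeric((ifelse(inc, b, 0)) %*% wrow)
    }
    eta <- intercept + covterm
    v <- rnorm(S, eta, d$sigma_theta[, l])
    out[, l] <- if (l <= 2) exp(v) else v
  }
  out
}

#' Bayesian p-value from predictive and observed draws
#'
#' Estimates `P = Pr(theta_pred - theta_obs <= 0)` by independently pairing
#' uniform resamples (with replacement) of the predictive-prior draws and
#' the stage-1 posterior draws that stand in for the unobservable random
#' effect.
#'
#' @param pred,obs numeric vectors, or matrices with matching columns (one
#'   p-value per column).
#' @param n_pairs number of resampled pairs (default: the larger draw
#'   count).
#' @return scalar or per-column named vector of p-values in `[0, 1]`.
#' @export
bayes_pvalue <- function(pred, obs, n_pairs = NULL) {
  if (is.matrix(pred) || is.matrix(obs)) {
    pred <- as.matrix(pred); obs <- as.matrix(obs)
    stopifnot(ncol(pred) == ncol(obs))
    return(vapply(seq_len(ncol(pred)), function(j)
      bayes_pvalue(pred[, j], obs[, j], n_pairs), numeric(1)))
  }
  stopifnot(length(pred) >= 1, length(obs) >= 1)
  if (is.null(n_pairs)) n_pairs <- max(length(pred), length(obs))
  ip <- sample.int(length(pred), n_pairs, replace = TRUE)
  io <- sample.int(length(obs), n_pairs, replace = TRUE)
  mean(pred[ip] - obs[io] <= 0)
}

#' Leave-one-profile-out model criticism
#'
#' Repeats only the (computationally cheap) second stage with each
#' profile's stage-1 draws excluded in turn, then computes a
#' predictive-prior Bayesian p-value per (profile, parameter). Stage 1 is
#' never re-run and the ODE solver is never touched. Under the true
#' sampling model the p-values are approximately Uniform(0, 1) — though not
#' independent across profiles — so quantile-quantile assessment against
#' uniformity ([qq_uniform()]) is the intended readout.
#'
#' @param store a full `stage1_store`.
#' @param dataset the [pk_dataset()].
#' @param spec a [model_spec()].
#' @param config a [stage2_config()] for each refit.
#' @param seed master seed (each refit derives its own).
#' @return object of class `crossval_result`: data frame `p_values`
#'   (`profile_id`, `parameter`, `p_value`) plus metadata.
#' @export
loo_assessment <- function(store, dataset, spec, config = stage2_config(),
                           seed = 1) {
  ids <- intersect(names(included_profiles(dataset)), names(store$entries))
  ids <- setdiff(ids, names(store$excluded))
  if (spec$covariates && is.null(spec$delta_beta)) {
    # fix the coefficient-prior widths once, from the full store, so every
    # leave-one-out refit uses the same prior
    spec$delta_beta <- delta_beta_from_store(store)
  }
  rows <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    store_k <- store
    store_k$entries[[id]] <- NULL
    fit <- run_stage2(store_k, dataset, spec, config,
                      seed = profile_seed(seed, 5000 + k))
    set.seed(profile_seed(seed, 6000 + k))
    pred <- predictive_prior_draws(fit, dataset, id)
    obs <- store$entries[[id]]$draws[, 1:4, drop = FALSE]
    p <- bayes_pvalue(pred, obs)
    rows[[k]] <- data.frame(profile_id = id, parameter = PARAM_NAMES[1:4],
                            p_value = as.numeric(p))
  }
  structure(list(p_values = do.call(rbind, rows), spec = spec,
                 config = config, seed = seed, n_profiles = length(ids)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("<crossval_result>", x$n_profiles, "leave-one-out refits (",
      x$spec$level, "level model )\n")
  ks <- qq_uniform(x$p_values$p_value)$ks
  cat("  KS distance of pooled p-values from Uniform(0,1):",
      round(ks, 3), "\n")
  invisible(x)
}

#' Quantile-quantile table against Uniform(0, 1)
#'
#' Plot-ready ordered pairs of theoretical and empirical quantiles, and the
#' Kolmogorov-Smirnov distance `sup |F_n(p) - p|`. The p-values feeding
#' this are not independent across profiles, so the KS distance is a
#' descriptive guide rather than a calibrated test statistic.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return list(`table` = data frame with `theoretical`, `empirical`;
#'   `ks` = KS distance).
#' @export
qq_uniform <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  n <- length(p_values)
  p <- sort(p_values)
  ks <- max(pmax(abs(seq_len(n) / n - p), abs((seq_len(n) - 1) / n - p)))
  list(table = data.frame(theoretical = seq_len(n) / (n + 1), empirical = p),
       ks = ks)
}
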