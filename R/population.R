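#' Population model specification
#'
#' Chooses one of the four hierarchy variants and whether covariate
#' selection is active, and fixes the prior constants: vague normal priors
#' for the global intercepts (sd 100 on the log scale for t_max and MCR,
#' 1000 for a and b), U(0, 100) priors on every sd, and the
#' `delta_beta / (1.96 * delta_x)` scaling of the coefficient-prior sds per
#' covariate group.
#'
#' @param level `"one"` (profiles exchangeable), `"two"` (woman-specific
#'   intercepts), `"threeV"` (visit-specific) or `"threeM"`
#'   (mealtime-specific).
#' @param covariates logical: reversible-jump covariate selection on?
#' @param delta_beta numeric(4): width of the plausible range of each
#'   kinetic parameter (log-parameter for t_max, MCR), used to scale the
#'   coefficient priors. Defaults, when `NULL`, to the range of stage-1
#'   posterior medians computed by [delta_beta_from_store()] at fit time.
#' @param phi_prior_sd prior sds for the global intercepts.
#' @param sd_upper upper bound of the uniform priors on all sds.
#' @export
model_spec <- function(level = c("one", "two", "threeV", "threeM"),
                       covariates = FALSE, delta_beta = NULL,
                       phi_prior_sd = c(100, 100, 1000, 1000),
                       sd_upper = 100) {
  level <- match.arg(level)
  if (!is.null(delta_beta)) {
    stopifnot(length(delta_beta) == 4)
    if (any(delta_beta <= 0)) stop("delta_beta must be positive")
  }
  structure(list(level = level, covariates = covariates,
                 delta_beta = delta_beta, phi_prior_sd = phi_prior_sd,
                 sd_upper = sd_upper),
            class = "model_spec")
}

#' Default coefficient-prior widths from the stage-1 store
#'
#' Sets `delta_beta[l]` to the range of the stage-1 posterior medians of the
#' l-th kinetic parameter across profiles (on the log scale for t_max and
#' MCR). An informative coefficient prior is essential because its sd
#' influences the inclusion probabilities; this reuses the data mildly, a
#' trade-off accepted by design.
#'
#' @param store a `stage1_store`.
#' @export
delta_beta_from_store <- function(store) {
  med <- t(vapply(store$entries, function(e)
    apply(e$draws[, 1:4, drop = FALSE], 2, median), numeric(4)))
  med[, 1] <- log(med[, 1]); med[, 2] <- log(med[, 2])
  db <- apply(med, 2, function(x) diff(range(x)))
  if (any(db <= 0)) stop("degenerate stage-1 medians; cannot set delta_beta")
  unname(db)
}

#' Coefficient-prior standard deviation for a covariate group
#'
#' `delta_beta / (1.96 * delta_x)`, where `delta_x` is the width of the
#' covariate range for the group: 1 for binary covariates (including
#' study-mealtime interactions) and `2 * 1.96 = 3.92` for standardized
#' continuous covariates, on the assumption that the extreme plausible
#' gradients delimit a 95% prior interval.
#'
#' @param delta_beta plausible-range width for the kinetic (log-)parameter.
#' @param group `"continuous"`, `"binary"` or `"interaction"`.
#' @export
coefficient_prior_sd <- function(delta_beta, group) {
  stopifnot(delta_beta > 0)
  dx <- switch(group, continuous = 2 * 1.96, binary = 1, interaction = 1,
               stop("unknown covariate group: ", group))
  delta_beta / (1.96 * dx)
}

#' Prior log-probability of a covariate sub-model
#'
#' For the continuous and binary groups, the sub-model dimension has a
#' Binomial(c_G, 1/2) prior and, given the dimension, all column subsets are
#' equally likely — so every sub-model in the group has prior probability
#' `0.5^c_G`. For the four study-mealtime interaction indicators the
#' dimension prior is (1/12, 4/12, 6/12, 1/12, 0) on q = 0..4: all four
#' indicators together would be unidentifiable (prior mass 0), and the four
#' three-indicator models are essentially the same model, so they share one
#' 1/12 slot (1/48 each); every distinct identifiable model then has
#' probability 1/12.
#'
#' @param group `"continuous"`, `"binary"` or `"interaction"`.
#' @param q sub-model dimension (number of selected columns).
#' @param gamma integer vector of selected column indices within the group
#'   (validated for uniqueness and range; its identity does not change the
#'   probability beyond `q`).
#' @param c_g number of candidate columns in the group.
#' @return log prior probability (`-Inf` for excluded models).
#' @export
model_prior_logpmf <- function(group, q, gamma, c_g) {
  stopifnot(q >= 0, q <= c_g, length(gamma) == q,
            !anyDuplicated(gamma), all(gamma >= 1 & gamma <= c_g))
  if (group == "interaction") {
    stopifnot(c_g == 4)
    pq <- c(1, 4, 6, 1, 0) / 12
    if (pq[q + 1] == 0) return(-Inf)
    log(pq[q + 1]) - lchoose(4, q)
  } else {
    stats::dbinom(q, c_g, 0.5, log = TRUE) - lchoose(c_g, q)
  }
}

#' Random-effect log-density
#'
#' The population distribution of the profile-level parameters: log-normal
#' (mean and sd on the log scale) for t_max and MCR (l = 1, 2), normal for
#' a and b (l = 3, 4).
#'
#' @param theta parameter value on the natural scale (positive for l = 1,2).
#' @param eta linear predictor (log scale for l = 1, 2).
#' @param sd_l residual sd of the population distribution.
#' @param l parameter index 1..4.
#' @export
random_effect_logpdf <- function(theta, eta, sd_l, l) {
  stopifnot(l %in% 1:4, sd_l > 0)
  if (l <= 2) {
    ifelse(theta > 0, dnorm(log(theta), eta, sd_l, log = TRUE) - log(theta),
           -Inf)
  } else {
    dnorm(theta, eta, sd_l, log = TRUE)
  }
}

# columns of the design belonging to each group, as indices into X
group_columns <- function(design) {
  list(continuous = which(design$group == "continuous"),
       binary = which(design$group == "binary"),
       interaction = which(design$group == "interaction"))
}

# covariate contribution W_l beta_l (length n) for parameter l given the
# selection state sel[[l]] = list(C/B/I -> list(gamma, beta)); gamma indexes
# columns of X directly
covariate_contribution <- function(sel_l, X) {
  out <- numeric(nrow(X))
  for (g in sel_l) {
    if (length(g$gamma))
      out <- out + as.numeric(X[, g$gamma, drop = FALSE] %*% g$beta)
  }
  out
}

#' Profile-level linear predictors
#'
#' Assembles `eta_ijkl` for every profile and parameter: the level's
#' intercept (global, woman, visit or mealtime) plus, when covariate
#' selection is active, the selected-covariate term `W_ijkl beta_l`.
#'
#' @param state population state: elements `phi` (length 4), `psi`/`chi`
#'   (intercept matrices, levels permitting) and, with covariates, `sel` —
#'   per parameter, per group, a list(`gamma`, `beta`) whose `gamma` holds
#'   column indices of `design$X` directly.
#' @param spec a [model_spec()].
#' @param struct hierarchy index structure (internal; built from the
#'   dataset's profiles).
#' @param design a `covariate_design` or `NULL`.
#' @return n x 4 matrix of linear predictors.
#' @export
linear_predictor <- function(state, spec, struct, design = NULL) {
  n <- length(struct$woman)
  eta <- matrix(0, n, 4)
  for (l in 1:4) {
    eta[, l] <- switch(spec$level,
      one = rep(state$phi[l], n),
      two = state$psi[struct$woman, l],
      threeV = state$chi[struct$visit, l],
      threeM = state$chi[struct$meal, l])
    if (spec$covariates && !is.null(design))
      eta[, l] <- eta[, l] + covariate_contribution(state$sel[[l]], design$X)
  }
  eta
}
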