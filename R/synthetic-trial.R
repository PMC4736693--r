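#' Synthetic CSII trial design
#'
#' Describes the generative setting for a synthetic insulin-aspart trial:
#' the study layout (women x visits x meals), dosing distributions, the meal
#' windows and sampling schedule, the true population model for the kinetic
#' parameters and the residual-error levels. Defaults emulate the scale of a
#' 22-woman, two-visit, two-meal CSII study: basal infusion with median
#' 0.6 U/h, prandial boluses with median 8.9 U delivered over 1 min, dinner
#' windows 17:30-23:00 on day 1 and breakfast windows 06:30-12:00 on day 2,
#' and dense post-meal sampling (every 10 min for 90 min, every 15 min to
#' 5 h, 30-min spacing otherwise).
#'
#' True kinetic values are physiologically scaled: typical time-to-peak
#' around 55 min and metabolic clearance around 0.025 l/kg/min, with
#' between-woman, between-visit and residual spreads chosen as
#' order-of-magnitude values. By default a faster absorption after breakfast
#' in the second study is injected through the study-mealtime interaction on
#' log t_max, mirroring the kind of effect such trials look for.
#'
#' @param n_women,visits_per_woman study size (default 22 x 2).
#' @param meals character subset of `c("dinner", "breakfast")`.
#' @param level true population structure: `"one"`, `"two"`, `"threeV"`
#'   (visit-specific intercepts) or `"threeM"` (mealtime-specific).
#' @param phi true global intercepts for (log t_max, log MCR, a, b).
#' @param sigma_theta,sigma_psi,sigma_chi true sds per parameter for the
#'   residual, between-woman and between-visit/meal levels (unused levels
#'   may stay at their defaults).
#' @param beta named list `l -> named numeric` of true covariate effects on
#'   the linear predictor of parameter `l` (names are design columns).
#' @param kappa_range,lam_range per-profile residual parameters are drawn
#'   uniformly from these ranges (pmol/l and dimensionless).
#' @param basal_median,basal_sdlog,bolus_median,bolus_sdlog log-normal dosing
#'   distributions (U/h and U).
#' @param covariates logical: generate the 13-factor clinical/demographic
#'   table (7 continuous, 4 binary factors plus study and mealtime)?
#' @export
trial_design <- function(n_women = 22, visits_per_woman = 2,
                         meals = c("dinner", "breakfast"),
                         level = "threeV",
                         phi = c(log(55), log(0.025), -0.03, 30),
                         sigma_theta = c(0.10, 0.10, 0.030, 6),
                         sigma_psi = c(0.12, 0.12, 0.030, 8),
                         sigma_chi = c(0.08, 0.08, 0.020, 5),
                         beta = list(`1` = c(study2_breakfast = -0.30),
                                     `3` = c(study2_breakfast = 0.09)),
                         kappa_range = c(3, 8), lam_range = c(0.04, 0.08),
                         basal_median = 0.6, basal_sdlog = 1.0,
                         bolus_median = 8.9, bolus_sdlog = 0.45,
                         covariates = TRUE) {
  stopifnot(n_women >= 1, visits_per_woman >= 1, length(meals) >= 1,
            all(meals %in% c("dinner", "breakfast")),
            level %in% c("one", "two", "threeV", "threeM"),
            length(phi) == 4, length(sigma_theta) == 4,
            all(sigma_theta >= 0), all(sigma_psi >= 0), all(sigma_chi >= 0))
  structure(list(n_women = n_women, visits_per_woman = visits_per_woman,
                 meals = meals, level = level, phi = phi,
                 sigma_theta = sigma_theta, sigma_psi = sigma_psi,
                 sigma_chi = sigma_chi, beta = beta,
                 kappa_range = kappa_range, lam_range = lam_range,
                 basal_median = basal_median, basal_sdlog = basal_sdlog,
                 bolus_median = bolus_median, bolus_sdlog = bolus_sdlog,
                 covariates = covariates),
            class = "trial_design")
}

# meal-window constants (minutes since midnight day 1)
MEAL_TIMES <- c(dinner = 1080, breakfast = 1890)          # 18:00 d1, 07:30 d2
WINDOWS <- list(dinner = c(1050, 1380),                    # 17:30 - 23:00 d1
                breakfast = c(1830, 2160))                 # 06:30 - 12:00 d2

#' Scheduled sampling times within a meal window
#'
#' Implements the trial's sampling rule: every 10 min for the first 90 min
#' post-meal, every 15 min from 1.5 h to 5 h post-meal, and 30-min spacing
#' before the meal. Post-meal grids are half-open on the left (first sample
#' 10 min after the meal); all times are truncated to the window.
#'
#' @param meal_time meal start, minutes; must lie inside the window.
#' @param window_start,window_end window bounds, minutes.
#' @return strictly increasing vector of sampling times.
#' @export
sampling_times <- function(meal_time, window_start, window_end) {
  stopifnot(window_start <= meal_time, meal_time < window_end)
  pre <- if (meal_time > window_start)
    seq(window_start, meal_time - 1e-9, by = 30) else numeric()
  g10 <- seq(meal_time + 10, meal_time + 90, by = 10)
  g15 <- seq(meal_time + 105, meal_time + 300, by = 15)
  tt <- sort(unique(c(pre, g10, g15)))
  tt[tt >= window_start & tt <= window_end]
}

# deterministic per-profile RNG substream so that subsetting profiles leaves
# the draws of the remaining profiles unchanged
profile_seed <- function(seed, p) {
  as.integer((as.numeric(seed) * 97 + p * 100003) %% 2147483629) + 1L
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate a complete synthetic trial
#'
#' Draws covariates, dosing schedules, true kinetic parameters from the
#' population model of the design, and noisy observations from the
#' two-compartment forward model, fully reproducibly from `seed`.
#'
#' @param design a [trial_design()].
#' @param seed integer master seed; woman-level quantities use one stream and
#'   each profile a derived substream.
#' @return list with elements `dataset` (a [pk_dataset()], with covariate
#'   design when `design$covariates`) and `truth` (true population
#'   parameters, per-profile `theta` on the natural scale, `ttheta` on the
#'   modelling scale, and per-profile `kappa`, `lam`).
#' @export
generate_trial <- function(design, seed) {
  stopifnot(inherits(design, "trial_design"))
  d <- design
  # total-sd support check against the stage-1 prior box
  tot_sd <- sqrt(d$sigma_theta^2 +
                   (if (d$level != "one") d$sigma_psi^2 else 0) +
                   (if (d$level %in% c("threeV", "threeM")) d$sigma_chi^2
                    else 0))
  p_out <- stats::pnorm(log(5), d$phi[1], tot_sd[1]) +
    stats::pnorm(log(500), d$phi[1], tot_sd[1], lower.tail = FALSE) +
    stats::pnorm(log(0.25), d$phi[2], tot_sd[2], lower.tail = FALSE)
  if (p_out > 1e-3)
    warning("design places non-negligible kinetic-parameter mass outside ",
            "the stage-1 prior supports (p = ", signif(p_out, 2), ")")

  set.seed(seed)
  N <- d$n_women
  study <- c(rep(1, ceiling(N * 10 / 22)), rep(2, N - ceiling(N * 10 / 22)))
  woman_cov <- data.frame(
    age = rnorm_trunc(N, 32, 4.5, 18, 45),
    bmi = rnorm_trunc(N, 27, 3.3, 18, 40),
    hba1c = rnorm_trunc(N, 7.1, 1.0, 5, 11),
    diabetes_duration = rnorm_trunc(N, 18, 8.6, 1, 40),
    total_daily_dose = rnorm_trunc(N, 55, 18, 15, 120),
    kings_college = as.numeric(runif(N) < 5 / 22),
    weight = rnorm_trunc(N, 75, 10, 50, 110)
  )
  gest_base <- rnorm_trunc(N, 18, 5, 8, 30)
  psi <- sapply(1:4, function(l) rnorm(N, d$phi[l], d$sigma_psi[l]))
  chi_v <- array(rnorm(N * d$visits_per_woman * 4), c(N, d$visits_per_woman, 4))
  for (l in 1:4) chi_v[, , l] <- psi[, l] + d$sigma_chi[l] * chi_v[, , l]
  chi_m <- array(rnorm(N * 2 * 4), c(N, 2, 4))   # meal index: dinner=1, bfast=2
  for (l in 1:4) chi_m[, , l] <- psi[, l] + d$sigma_chi[l] * chi_m[, , l]
  basal_rate <- matrix(exp(rnorm(N * d$visits_per_woman, log(d$basal_median),
                                 d$basal_sdlog)), N)
  basal_rate <- pmin(pmax(basal_rate, 0.05), 3)

  profiles <- list(); fac_rows <- list(); truth_rows <- list()
  p <- 0
  for (i in seq_len(N)) for (j in seq_len(d$visits_per_woman))
    for (meal in d$meals) {
      p <- p + 1
      set.seed(profile_seed(seed, p))
      k <- match(meal, c("dinner", "breakfast"))
      mt <- MEAL_TIMES[[meal]]; win <- WINDOWS[[meal]]
      dose <- min(max(exp(rnorm(1, log(d$bolus_median), d$bolus_sdlog)), 1), 30)
      longer <- runif(1) < 8 / 88
      multi <- runif(1) < 17 / 88
      closed_loop <- runif(1) < 24 / 88
      peak_rate <- max(rnorm(1, 9.3, 5.0), 0.5)
      gest <- min(max(gest_base[i] +
                        (j - 1) * (if (study[i] == 1) 14 else 3), 8), 38)
      bol <- data.frame(start = mt, duration = if (longer) 15 else 1,
                        dose = dose)
      if (multi) bol <- rbind(bol, data.frame(start = mt + 60, duration = 1,
                                              dose = 0.3 * dose))
      sched <- dosing_schedule(
        basal = data.frame(start = 0, end = 2160, rate = basal_rate[i, j]),
        bolus = bol)
      # linear predictor on the modelling scale
      eta <- switch(d$level,
                    one = d$phi,
                    two = psi[i, ],
                    threeV = chi_v[i, j, ],
                    threeM = chi_m[i, k, ])
      cell <- paste0("study", study[i], "_", meal)
      fac <- list(age = woman_cov$age[i], bmi = woman_cov$bmi[i],
                  hba1c = woman_cov$hba1c[i],
                  diabetes_duration = woman_cov$diabetes_duration[i],
                  gestation = gest,
                  total_daily_dose = woman_cov$total_daily_dose[i],
                  peak_bolus_rate = peak_rate,
                  kings_college = woman_cov$kings_college[i],
                  longer_bolus = as.numeric(longer),
                  multiple_boluses = as.numeric(multi),
                  closed_loop = as.numeric(closed_loop),
                  study = study[i], meal = meal)
      # injected effects are per standardized unit for continuous factors
      # (standardized against the nominal trial means/sds) and per unit
      # indicator for binary and study-mealtime columns
      nominal <- list(age = c(32, 4.5), bmi = c(27, 3.3), hba1c = c(7.1, 1.0),
                      diabetes_duration = c(18, 8.6), gestation = c(22, 6.5),
                      total_daily_dose = c(55, 18),
                      peak_bolus_rate = c(9.3, 5.0))
      bshift <- vapply(1:4, function(l) {
        bl <- d$beta[[as.character(l)]]
        if (is.null(bl)) return(0)
        s <- 0
        for (nm in names(bl)) {
          val <- if (nm %in% names(nominal)) {
            (fac[[nm]] - nominal[[nm]][1]) / nominal[[nm]][2]
          } else if (nm %in% names(fac)) {
            as.numeric(fac[[nm]])
          } else if (startsWith(nm, "study")) {
            as.numeric(cell == nm)
          } else stop("unknown covariate in design beta: ", nm)
          s <- s + bl[[nm]] * val
        }
        s
      }, numeric(1))
      ttheta <- rnorm(4, eta + bshift, d$sigma_theta)
      theta <- c(exp(ttheta[1]), exp(ttheta[2]), ttheta[3], ttheta[4])
      kap <- runif(1, d$kappa_range[1], d$kappa_range[2])
      lam <- runif(1, d$lam_range[1], d$lam_range[2])
      tt <- sampling_times(mt, win[1], win[2])
      params <- kinetic_params(theta[1], theta[2], theta[3], theta[4])
      ctx <- profile_context(woman_cov$weight[i], mt + 300, win[1])
      sol <- integrate_compartments(sched, theta[1], tt)
      mu <- predicted_concentration(params, ctx, tt, sol$Q2)
      y <- rnorm(length(tt), mu, sqrt(kap^2 + lam^2 * mu^2))
      prof <- pk_profile(i, j, meal, tt, y, sched, woman_cov$weight[i],
                         mt + 300, win[1])
      profiles[[prof$profile_id]] <- prof
      fac_rows[[p]] <- data.frame(profile_id = prof$profile_id, fac,
                                  stringsAsFactors = FALSE)
      truth_rows[[p]] <- data.frame(profile_id = prof$profile_id,
                                    t(setNames(theta,
                                               c("t_max", "mcr", "a", "b"))),
                                    kappa = kap, lam = lam)
    }

  facs <- do.call(rbind, fac_rows)
  des <- NULL
  if (d$covariates) {
    types <- c(age = "continuous", bmi = "continuous", hba1c = "continuous",
               diabetes_duration = "continuous", gestation = "continuous",
               total_daily_dose = "continuous", peak_bolus_rate = "continuous",
               kings_college = "binary", longer_bolus = "binary",
               multiple_boluses = "binary", closed_loop = "binary")
    des <- build_design(facs, types)
  }
  dataset <- pk_dataset(profiles, des)
  truth <- list(level = d$level, phi = d$phi, sigma_theta = d$sigma_theta,
                sigma_psi = d$sigma_psi, sigma_chi = d$sigma_chi,
                beta = d$beta, psi = psi,
                per_profile = do.call(rbind, truth_rows),
                factors = facs)
  list(dataset = dataset, truth = truth)
}
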