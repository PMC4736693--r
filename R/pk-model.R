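#' Profile-level kinetic parameters
#'
#' The four unknowns of the profile-level model: `t_max`, the time-to-peak
#' plasma insulin concentration in minutes (also the inverse rate constant of
#' both subcutaneous compartments); `mcr`, the metabolic clearance rate in
#' l/kg/min; and the residual-insulin drift, which changes concentration at
#' rate `a` (pmol/l/min) and equals `b` (pmol/l) at the 5-h post-meal
#' reference time.
#'
#' @param t_max time-to-peak, minutes; must be positive.
#' @param mcr metabolic clearance rate, l/kg/min; must be positive.
#' @param a residual-insulin accumulation rate, pmol/l/min (any sign).
#' @param b post-prandial residual concentration, pmol/l (any sign).
#' @export
kinetic_params <- function(t_max, mcr, a = 0, b = 0) {
  stopifnot(is.finite(t_max), t_max > 0, is.finite(mcr), mcr > 0,
            is.finite(a), is.finite(b))
  structure(list(t_max = t_max, mcr = mcr, a = a, b = b),
            class = "kinetic_params")
}

#' Profile context (observed per-profile data)
#'
#' @param wt body weight, kg.
#' @param t_end 5-h post-meal reference time, minutes.
#' @param t_start trial start time, minutes (integration always starts at
#'   t = 0, midnight of day 1, so states at `t_start` are input-determined).
#' @param unit_conversion pmol per mU of insulin mass. The default 6 pmol/mU
#'   corresponds to 1 U = 6 nmol of insulin; it is configurable because
#'   assay/analogue conventions differ.
#' @export
profile_context <- function(wt, t_end, t_start = 0, unit_conversion = 6) {
  stopifnot(wt > 0, t_start < t_end, unit_conversion > 0)
  structure(list(wt = wt, t_end = t_end, t_start = t_start,
                 unit_conversion = unit_conversion),
            class = "profile_context")
}

#' Residual-variance nuisance parameters
#'
#' `kappa` is the additive residual sd (pmol/l), `lam` the multiplicative
#' coefficient; the residual variance at modelled concentration `mu` is
#' `kappa^2 + lam^2 * mu^2`. `lam` is bounded by 1 because residuals larger
#' in magnitude than the modelled concentration are implausible here.
#'
#' @param kappa additive sd in `[0, 100]`.
#' @param lam multiplicative coefficient in `[0, 1]`.
#' @export
nuisance_params <- function(kappa, lam) {
  stopifnot(kappa >= 0, kappa <= 100, lam >= 0, lam <= 1)
  structure(list(kappa = kappa, lam = lam), class = "nuisance_params")
}

#' Integrate the two-compartment absorption model
#'
#' Solves dQ1/dt = r(t) - Q1/t_max, dQ2/dt = (Q1 - Q2)/t_max from
#' Q1(0) = Q2(0) = 0 with the piecewise-constant input implied by `dosing`,
#' using an adaptive embedded Cash-Karp 4(5) Runge-Kutta pair. Every dosing
#' discontinuity is a forced step boundary so the local error estimate never
#' straddles a jump in the input rate.
#'
#' @param dosing a [dosing_schedule()].
#' @param t_max compartment time constant, minutes.
#' @param times sorted non-negative output times, minutes.
#' @param rtol,atol relative and absolute (mU) integration tolerances.
#' @return data frame with columns `time`, `Q1`, `Q2` (mU); attributes
#'   `n_steps` and `n_reject` record solver effort.
#' @seealso [closed_form_compartments()] for the exact per-segment solution
#'   used as an independent oracle in the test suite.
#' @export
integrate_compartments <- function(dosing, t_max, times,
                                   rtol = 1e-6, atol = 1e-6) {
  stopifnot(t_max > 0, !is.unsorted(times), all(times >= 0))
  pw <- dosing_breaks(dosing)
  sol <- ck_solve_cpp(as.numeric(times), t_max, pw$breaks, pw$rates,
                      rtol, atol)
  out <- data.frame(time = as.numeric(times), Q1 = sol$Q1, Q2 = sol$Q2)
  attr(out, "n_steps") <- sol$n_steps
  attr(out, "n_reject") <- sol$n_reject
  out
}

#' Exact compartment states for piecewise-constant input
#'
#' Analytic propagation of (Q1, Q2) across each constant-input segment. With
#' constant input r and rate constant k = 1/t_max over an interval of length
#' d starting from (Q1_0, Q2_0):
#' \deqn{Q1 = r/k + (Q1_0 - r/k) e^{-kd}}
#' \deqn{Q2 = r/k + e^{-kd}\{(Q2_0 - r/k) + k d (Q1_0 - r/k)\}}
#' This is exact (the system is linear) and serves as the independent oracle
#' for [integrate_compartments()].
#'
#' @inheritParams integrate_compartments
#' @return data frame with columns `time`, `Q1`, `Q2` (mU).
#' @export
closed_form_compartments <- function(dosing, t_max, times) {
  stopifnot(t_max > 0, !is.unsorted(times), all(times >= 0))
  pw <- dosing_breaks(dosing)
  k <- 1 / t_max
  prop <- function(q1, q2, r, d) {
    e <- exp(-k * d)
    rk <- r / k
    c(rk + (q1 - rk) * e,
      rk + e * ((q2 - rk) + k * d * (q1 - rk)))
  }
  edges <- sort(unique(c(0, pw$breaks, times)))
  q <- c(0, 0)
  state_at <- setNames(vector("list", length(edges)), NULL)
  for (i in seq_along(edges)) {
    if (i > 1) {
      t0 <- edges[i - 1]; t1 <- edges[i]
      r <- 0
      if (length(pw$rates)) {
        mid <- (t0 + t1) / 2
        if (mid >= pw$breaks[1] && mid < pw$breaks[length(pw$breaks)]) {
          r <- pw$rates[findInterval(mid, pw$breaks)]
        }
      }
      q <- prop(q[1], q[2], r, t1 - t0)
    }
    state_at[[i]] <- q
  }
  m <- do.call(rbind, state_at)
  idx <- match(times, edges)
  data.frame(time = as.numeric(times), Q1 = m[idx, 1], Q2 = m[idx, 2])
}

#' Predicted plasma insulin concentration
#'
#' The regression function: plasma concentration equilibrates instantaneously
#' with the efflux from compartment 2, `Q2/(t_max * wt * mcr)` (mass converted
#' mU to pmol), plus the linear residual-insulin term `a*(t - t_end) + b`.
#'
#' @param params a [kinetic_params()].
#' @param ctx a [profile_context()].
#' @param t observation time(s), minutes.
#' @param Q2 compartment-2 insulin mass (mU) at `t`, computed with the same
#'   `t_max` as in `params`.
#' @return concentration(s), pmol/l.
#' @export
predicted_concentration <- function(params, ctx, t, Q2) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(ctx, "profile_context"), length(t) == length(Q2))
  ctx$unit_conversion * Q2 / (params$t_max * ctx$wt * params$mcr) +
    params$a * (t - ctx$t_end) + params$b
}

#' Profile log-likelihood
#'
#' Gaussian observation model with combined additive and multiplicative
#' variance: `y_m ~ N(mu_m, kappa^2 + lam^2 * mu_m^2)` where `mu_m` is the
#' predicted concentration at the m-th observation time.
#'
#' @param obs data frame (or list) with elements `times` and `conc`.
#' @param params a [kinetic_params()].
#' @param nuis a [nuisance_params()].
#' @param ctx a [profile_context()].
#' @param dosing a [dosing_schedule()].
#' @param rtol,atol integration tolerances passed to the ODE solver.
#' @return scalar log-density.
#' @export
log_likelihood <- function(obs, params, nuis, ctx, dosing,
                           rtol = 1e-6, atol = 1e-6) {
  stopifnot(length(obs$times) >= 1, length(obs$times) == length(obs$conc))
  ord <- order(obs$times)   # observation order is immaterial
  obs <- list(times = obs$times[ord], conc = obs$conc[ord])
  sol <- integrate_compartments(dosing, params$t_max, obs$times, rtol, atol)
  mu <- predicted_concentration(params, ctx, obs$times, sol$Q2)
  s2 <- nuis$kappa^2 + nuis$lam^2 * mu^2
  if (any(s2 <= 0)) {
    stop("degenerate residual variance: kappa^2 + lam^2 * mu^2 = 0 at ",
         "observation time ", obs$times[which(s2 <= 0)[1]])
  }
  sum(dnorm(obs$conc, mean = mu, sd = sqrt(s2), log = TRUE))
}

#' ODE solver instrumentation
#'
#' `ode_call_count()` returns the number of compartment-model integrations
#' performed since the last [ode_call_reset()]. Stage 2 of the two-stage
#' scheme must leave this counter untouched: the profile likelihood cancels
#' from its acceptance ratios, which is the source of its speed.
#' @return `ode_call_count()`: a count (numeric scalar).
#' @export
ode_call_count <- function() ode_call_count_cpp()

#' @rdname ode_call_count
#' @export
ode_call_reset <- function() invisible(ode_call_reset_cpp())
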