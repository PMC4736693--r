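#' Insulin dosing schedule
#'
#' Represents the exogenous insulin input for one profile: basal infusion
#' segments (piecewise-constant rates) plus prandial boluses modelled as
#' square pulses of finite duration (1 min by default in the trial design;
#' longer deliveries are represented by longer durations). Times are minutes
#' since midnight of day 1, continuous across study days.
#'
#' @param basal data frame with columns `start`, `end` (minutes) and `rate`
#'   (U/h). Segments must be non-overlapping with `start < end`.
#' @param bolus data frame with columns `start`, `duration` (minutes) and
#'   `dose` (U). `duration > 0`, `dose >= 0`.
#' @return An object of class `dosing_schedule`. Internally all inputs are
#'   held in mU: basal rates in mU/min, bolus doses in mU.
#' @examples
#' dosing_schedule(
#'   basal = data.frame(start = 0, end = 1440, rate = 0.6),
#'   bolus = data.frame(start = 1080, duration = 1, dose = 8.9)
#' )
#' @export
dosing_schedule <- function(basal = NULL, bolus = NULL) {
  if (is.null(basal)) {
    basal <- data.frame(start = numeric(), end = numeric(), rate = numeric())
  }
  if (is.null(bolus)) {
    bolus <- data.frame(start = numeric(), duration = numeric(),
                        dose = numeric())
  }
  stopifnot(all(c("start", "end", "rate") %in% names(basal)),
            all(c("start", "duration", "dose") %in% names(bolus)))
  basal <- basal[order(basal$start), , drop = FALSE]
  if (nrow(basal)) {
    if (any(basal$start < 0) || any(basal$end <= basal$start))
      stop("basal segments need 0 <= start < end")
    if (nrow(basal) > 1 &&
        any(basal$start[-1] < basal$end[-nrow(basal)] - 1e-9))
      stop("basal segments must not overlap")
    if (any(basal$rate < 0)) stop("basal rates must be non-negative")
  }
  if (nrow(bolus)) {
    if (any(bolus$start < 0)) stop("bolus start times must be non-negative")
    if (any(bolus$duration <= 0)) stop("bolus durations must be positive")
    if (any(bolus$dose < 0)) stop("bolus doses must be non-negative")
  }
  out <- list(
    basal = data.frame(start = basal$start, end = basal$end,
                       rate_mU_min = basal$rate * 1000 / 60),
    bolus = data.frame(start = bolus$start, duration = bolus$duration,
                       dose_mU = bolus$dose * 1000)
  )
  class(out) <- "dosing_schedule"
  out
}

#' @export
print.dosing_schedule <- function(x, ...) {
  cat("<dosing_schedule>", nrow(x$basal), "basal segment(s),",
      nrow(x$bolus), "bolus event(s)\n")
  invisible(x)
}

# piecewise-constant representation: breakpoints b_0 < ... < b_m and the
# constant rate (mU/min) on each [b_i, b_{i+1})
dosing_breaks <- function(dosing) {
  stopifnot(inherits(dosing, "dosing_schedule"))
  edges <- c(0, dosing$basal$start, dosing$basal$end,
             dosing$bolus$start, dosing$bolus$start + dosing$bolus$duration)
  edges <- sort(unique(edges))
  if (length(edges) < 2) return(list(breaks = c(0, 0), rates = numeric()))
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  rates <- vapply(mid, function(t) {
    r <- 0
    if (nrow(dosing$basal)) {
      hit <- t >= dosing$basal$start & t < dosing$basal$end
      r <- r + sum(dosing$basal$rate_mU_min[hit])
    }
    if (nrow(dosing$bolus)) {
      hit <- t >= dosing$bolus$start &
        t < dosing$bolus$start + dosing$bolus$duration
      r <- r + sum(dosing$bolus$dose_mU[hit] / dosing$bolus$duration[hit])
    }
    r
  }, numeric(1))
  list(breaks = edges, rates = rates)
}

#' Instantaneous insulin input rate
#'
#' Total input rate Inf(t) + Bol(t) entering compartment 1, in mU/min:
#' the basal rate active at `t` plus `dose/duration` for every bolus whose
#' square pulse covers `t`. Piecewise constant and right-continuous at event
#' starts; zero outside all segments.
#'
#' @param t time(s) in minutes (vectorized), `t >= 0`.
#' @param dosing a [dosing_schedule()].
#' @return numeric vector of rates (mU/min).
#' @export
input_rate <- function(t, dosing) {
  stopifnot(all(t >= 0))
  pw <- dosing_breaks(dosing)
  vapply(t, function(tt) {
    if (length(pw$rates) == 0 || tt < pw$breaks[1] ||
        tt >= pw$breaks[length(pw$breaks)]) return(0)
    i <- findInterval(tt, pw$breaks, rightmost.closed = FALSE)
    pw$rates[i]
  }, numeric(1))
}
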