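# shared fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a random piecewise-constant schedule for integrator property tests
random_schedule <- function() {
  n_seg <- sample(1:3, 1)
  starts <- sort(runif(n_seg, 0, 800))
  ends <- starts + runif(n_seg, 30, 300)
  ends <- pmin(ends, c(starts[-1], 1200) - 1e-3)
  keep <- ends > starts
  n_bol <- sample(0:2, 1)
  dosing_schedule(
    basal = if (any(keep)) data.frame(start = starts[keep],
                                      end = ends[keep],
                                      rate = runif(sum(keep), 0.1, 2)),
    bolus = if (n_bol > 0) data.frame(start = runif(n_bol, 0, 1000),
                                      duration = runif(n_bol, 1, 20),
                                      dose = runif(n_bol, 1, 15)))
}

max_rel_err <- function(a, b, floor = 1) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# small fast run configurations
quick_s1 <- function() stage1_config(burn_in = 1500, iterations = 5000,
                                     thin = 10, n_chains = 2)
quick_s2 <- function() stage2_config(iterations = 1500, burn_in = 500,
                                     thin = 1)

# an 8-profile dataset (4 women x 2 visits x 1 meal), one-level truth,
# no covariates: the workhorse for stage-2 behaviour tests
small_trial <- function() memo("small_trial", function() {
  des <- trial_design(n_women = 4, visits_per_woman = 2, meals = "dinner",
                      level = "one",
                      sigma_theta = c(0.15, 0.15, 0.04, 8),
                      beta = list(), covariates = FALSE)
  generate_trial(des, seed = 2024)
})

small_store <- function() memo("small_store", function() {
  run_stage1_all(small_trial()$dataset, quick_s1(), seed = 11)
})

# empirical KS distance between draws and a reference CDF given on a grid
ks_vs_grid <- function(draws, grid, cdf) {
  f <- stats::approxfun(grid, cdf, yleft = 0, yright = 1, rule = 2)
  x <- sort(draws)
  n <- length(x)
  max(pmax(abs(seq_len(n) / n - f(x)), abs((seq_len(n) - 1) / n - f(x))))
}
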