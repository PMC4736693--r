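---
title: "Two-stage Bayesian hierarchical modelling of subcutaneous insulin kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Bayesian hierarchical modelling of subcutaneous insulin kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostagepk)
```

## The problem

Continuous subcutaneous insulin infusion (CSII, pump therapy) trials produce
*profiles*: meal-window time series of plasma insulin concentration for one
woman at one meal of one visit, together with the pump's dosing record
(basal infusion segments plus prandial boluses) and a table of clinical and
demographic factors. The scientific questions are pharmacokinetic — how
fast is insulin absorbed and cleared, how reproducible are these quantities
within and between patients, and which clinical factors move them — and the
natural statistical frame is a Bayesian hierarchical nonlinear
mixed-effects model. Fitting that model directly is expensive because the
profile-level regression function is the solution of a differential
equation, and model *exploration* (different hierarchy depths, covariate
subsets, leave-one-out refits) multiplies that expense by the number of
models considered. This package implements a two-stage scheme that pays
the ODE cost once and then explores population models essentially for
free.

## Profile-level model

Insulin mass passes through two subcutaneous compartments with a common
first-order rate constant $1/t^{\max}$:

$$\dot Q_1(t) = \mathrm{Inf}(t) + \mathrm{Bol}(t) - Q_1(t)/t^{\max},
\qquad \dot Q_2(t) = \{Q_1(t) - Q_2(t)\}/t^{\max},$$

with $Q_1(0)=Q_2(0)=0$ at midnight of day 1, so that by the start of the
meal window the states are determined by the recorded dosing alone
(the run-in). $t^{\max}$ is interpretable as the time-to-peak plasma
concentration: the impulse response of $Q_2$ is
$D\,(t/t^{\max})e^{-t/t^{\max}}$, which peaks exactly at $t^{\max}$.
Plasma concentration equilibrates instantaneously with the efflux from
compartment 2 and carries a linear *residual insulin* drift absorbing any
long-acting insulin taken before the study:

$$\mu(\theta, z, t) = \frac{c\, Q_2(t)}{t^{\max}\, wt\, \mathrm{MCR}}
  + a\,(t - t^{\mathrm{end}}) + b,$$

with $\theta = (t^{\max}, \mathrm{MCR}, a, b)$, body weight $wt$, the 5-h
post-meal reference time $t^{\mathrm{end}}$, and $c$ the mass-to-molar
conversion. There is no single standard mass-to-molar factor across
insulin assay conventions; we default to $c = 6$ pmol per mU
(1 U $=$ 6 nmol) and expose it as a configurable constant of
`profile_context()`. Observations are Gaussian
with combined additive and multiplicative error,
$y \sim N(\mu, \kappa^2 + \lambda^2 \mu^2)$; $\lambda \le 1$ because
residuals larger than the modelled concentration are implausible here.

Equations are integrated with an embedded Cash–Karp 4(5) Runge–Kutta pair
(relative and absolute tolerances $10^{-6}$), with every dosing
discontinuity a forced step boundary so the embedded error estimate never
straddles a jump in the input rate. Because the input is piecewise
constant the linear system also has an exact per-segment solution
(`closed_form_compartments()`); it is kept strictly as an independent test
oracle — the fitted path always goes through the adaptive integrator, and
the test suite holds the two to within $10^{-5}$ relative error on
randomized schedules.

## Population models and priors

Each component $l$ of $\theta$ gets its own population distribution —
log-normal for $t^{\max}$ and MCR, normal for $a$ and $b$ — deliberately
avoiding a multivariate random-effects covariance, whose usual
inverse-Wishart prior is more informative than it looks with multiple
variance levels and small within-level sample sizes. Four hierarchies are
supported: one-level (profiles exchangeable), two-level (woman-specific
intercepts), and two three-level variants with visit- or mealtime-specific
intercepts; each optionally carries covariate effects in its lowest-level
linear predictor.

Priors: global intercepts $N(0, 100^2)$ on the log scale for $l = 1, 2$
and $N(0, 1000^2)$ for $l = 3, 4$; all sds uniform on $(0, 100)$;
$\kappa \sim U(0,100)$, $\lambda \sim U(0,1)$. Covariates are standardized
(continuous) or 0/1 (binary, study-mealtime interaction indicators), and
each (parameter, group) block carries its own coefficient prior sd
$\Delta\beta_l / (1.96\,\Delta x)$ with $\Delta x = 1$ for binary and
interaction columns and $3.92$ for standardized continuous columns; by
default $\Delta\beta_l$ is the range of the stage-1 posterior medians
(`delta_beta_from_store()`), a mild double use of the data accepted
because an informative coefficient prior is what makes inclusion
probabilities meaningful. Sub-model priors make every distinct
identifiable model equally likely within each group: Binomial$(c_G, 1/2)$
dimension priors with uniform subset choice for continuous and binary
groups, and the dimension pmf $(1, 4, 6, 1, 0)/12$ for the four
interaction indicators — all four indicators together would be
unidentifiable, and the four three-indicator labellings are one model
(kept as four states of prior mass $1/48$ each, preserving both the state
space's simplicity and uniformity over distinct models).

## Two-stage inference

Stage 1 (`run_stage1()`) fits every profile independently under flat
priors ($t^{\max} \sim U(5, 500)$, $\mathrm{MCR} \sim U(0, 0.25)$,
$a, b \sim N(0, 100^2)$) by componentwise adaptive random-walk Metropolis
on transformed scales, with the 0.44 acceptance target and adaptation
frozen after burn-in so the sampling kernel satisfies detailed balance.
The regression curve is re-solved only when $t^{\max}$ changes: one ODE
solve per $t^{\max}$ proposal is the cost contract. Two chains from
dispersed starts feed the Brooks–Gelman–Rubin diagnostic; profiles with
BGR above 1.1 on a kinetic parameter, or with more than 5% of posterior
mass within 1% of a kinetic prior bound, are flagged unfittable and
excluded — a reproducible proxy for the practice of dropping profiles the
profile-level model cannot fit. The thinned draws are the *store*.

Stage 2 (`run_stage2()`) runs the full hierarchical model with a
systematic scan: conjugate Gibbs for every intercept, stepping-out slice
sampling for every sd, a resampling Metropolis–Hastings step for each
profile's parameters, and one reversible-jump update of each of the 12
(parameter × group) selection blocks. The resampling step proposes a
uniformly chosen stored stage-1 draw; because the proposal density is the
stage-1 posterior itself, the profile likelihood and the nuisance priors
cancel, leaving the population-density ratio times the stage-1 prior
ratio. The uniform prior components cancel exactly within support; the
$N(0, 100^2)$ components for $a$ and $b$ are retained exactly rather than
approximated away — exactness costs one subtraction. $\kappa$ and
$\lambda$ never enter the ratio and are not updated. Stage 2 therefore
performs *zero* ODE solves, which the package asserts with an instrumented
solver counter, and the test suite verifies that arbitrarily perturbing
the stored nuisance draws leaves every acceptance decision bit-identical.
The central validity check, run as part of the acceptance suite, fits the
same 8-profile synthetic dataset with stage 1 + stage 2 and with a direct
single-stage sampler that evaluates the ODE likelihood at every sweep:
posterior means of all $\varphi_l$ and $\sigma_{\theta l}$ agree within
0.1 pooled posterior sd and the draw sets have Kolmogorov–Smirnov distance
below 0.1.

Reversible-jump moves are add / delete / swap / coefficient-refresh, drawn
uniformly from the valid menu; entering coefficients are proposed from
their prior (so their prior density cancels in the ratio), the refresh
move is a conjugate Gibbs draw, and swap ties are broken uniformly over
(in, out) pairs. No particular jump construction is canonical for this
problem; this simple menu is valid, adequate at $n = 88$, and documented
as replaceable. A flat-likelihood chain recovers the uniform
$1/12$ prior over the 12 distinct interaction models within Monte Carlo
error (batch-means standard errors), which exercises the
trans-dimensional balance directly.

## Model criticism

Leave-one-profile-out criticism (`loo_assessment()`) repeats only stage 2
with each profile's stage-1 draws removed. The discrepancy is defined on
the random-effect scale — response-scale checks would be masked by
observation error — as $D = \theta^{\mathrm{pred}} - \theta^{\mathrm{obs}}$,
where $\theta^{\mathrm{pred}}$ comes from the predictive prior (population
draws fitted without the profile, pushed through the omitted profile's
covariate row and hierarchy position) and the unobservable
$\theta^{\mathrm{obs}}$ is stood in for by the profile's stage-1 posterior
draws. $P = \Pr(D \le 0)$ is estimated by independent uniform resampling
of both draw sets, with replacement, defaulting to as many pairs as the
larger set. When the omitted profile's visit or meal intercept is
identified by a sibling profile the fitted intercept is used; otherwise a
fresh intercept is drawn from its population distribution — the literal
reading of the predictive-prior integral. Under the true model the
p-values are approximately uniform (they are not independent across
profiles), so the package reports quantile–quantile tables and a KS
distance rather than a formal test.

## The synthetic trial generator

`generate_trial()` emulates the study design the analysis assumes: 22
women × 2 visits × 2 meals (88 profiles), dinner windows 17:30–23:00 on
day 1 and breakfast windows 06:30–12:00 on day 2, sampling every 10 min
for 90 min post-meal, every 15 min to 5 h, and 30-min spacing pre-meal
(post-meal grids half-open on the left; exact sample times are not
specified by the trial description, so the grid convention is ours).
Basal rates are log-normal with median 0.6 U/h and boluses log-normal with
median 8.9 U delivered over 1 min (longer deliveries supported), matching
the trial's descriptive statistics; covariates are drawn to match the
reported factor means/sds and indicator frequencies. Typical kinetics are
physiologically scaled ($t^{\max} \approx 55$ min,
$\mathrm{MCR} \approx 0.025$ l/kg/min); the between-level sd defaults are
order-of-magnitude choices (no reference values exist for them) and every
generated quantity is recorded as ground truth for recovery testing. The
generator places the dinner meal and bolus at 18:00 on day 1 and the
breakfast meal at 07:30 on day 2, so both meals sit inside their windows
with dense post-meal sampling (4.5 h for breakfast). One master seed
drives woman-level draws, and each
profile derives its own substream, so subsetting profiles does not change
the others.

What passing on synthetic data does *not* show: the generator draws from
exactly the model family the fit assumes (Gaussian errors, log-normal
random effects, time-invariant covariates, square-pulse boluses). Real
trials add assay artefacts, model misspecification, missed dose records
and informative exclusions; results here validate the *machinery*, not
the clinical conclusions.

## Numerical choices and problem sizes

Tolerances $10^{-6}$ (relative and absolute) for the integrator; step-size
growth clipped to $[0.1, 5]$ per step; states clamped to zero when within
absolute tolerance below it. Stage-1 defaults (5 000 burn-in, 20 000
iterations, thin 20, two chains) are a working scale — production analyses
would run an order of magnitude longer; the test suite runs scaled-down
but converged chains (checked against grid oracles and by BGR) so the
whole suite completes in minutes on one CPU: the equivalence check uses 8
profiles with ~65 000 stage-2 sweeps, the recovery check 88 profiles with
4 000 sweeps, coverage 20 replicates of 12 profiles, and the
leave-one-out calibration 12 profiles. Degenerate inputs are handled
explicitly: zero residual variance is an error, not a silent `-Inf`;
empty dosing yields zero compartments; a store with a single draw per
profile pins the profile parameters while the population parameters keep
mixing.

## Known limitations

Profile parameters are resampled only among stored stage-1 atoms, so
stage-2 accuracy depends on the store covering the region the population
model favours (mitigated by flat stage-1 priors and checked by the
direct-sampler comparison). The RJ menu uses prior proposals for entering
coefficients, which is simple but not optimal for very strong effects;
inclusion probabilities mix more slowly than intercepts, and multi-chain
runs (`run_stage2_chains()`) are advisable for reporting. No multivariate
random-effects covariance, woman-specific covariate slopes, time-varying
covariates, or missing-data handling — all deliberate scope choices of the
methodology this package implements.
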