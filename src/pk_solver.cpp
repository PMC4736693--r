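#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-compartment subcutaneous insulin kinetics:
//   dQ1/dt = r(t) - Q1/tmax
//   dQ2/dt = (Q1 - Q2)/tmax
// with r(t) piecewise constant (basal infusion + square-pulse boluses, mU/min).
// Solved by the embedded Cash-Karp 4(5) Runge-Kutta pair with adaptive step
// size; every discontinuity of r(t) is a forced step boundary so the local
// error estimate is never taken across a jump in the input.

static long long g_ode_calls = 0;

// [[Rcpp::export]]
double ode_call_count_cpp() { return (double) g_ode_calls; }

// [[Rcpp::export]]
void ode_call_reset_cpp() { g_ode_calls = 0; }

static inline void rhs(double r, double inv_tmax, double q1, double q2,
                       double &d1, double &d2) {
  d1 = r - q1 * inv_tmax;
  d2 = (q1 - q2) * inv_tmax;
}

// Cash-Karp tableau
static const double B21 = 1.0 / 5.0;
static const double B31 = 3.0 / 40.0, B32 = 9.0 / 40.0;
static const double B41 = 3.0 / 10.0, B42 = -9.0 / 10.0, B43 = 6.0 / 5.0;
static const double B51 = -11.0 / 54.0, B52 = 5.0 / 2.0, B53 = -70.0 / 27.0,
                    B54 = 35.0 / 27.0;
static const double B61 = 1631.0 / 55296.0, B62 = 175.0 / 512.0,
                    B63 = 575.0 / 13824.0, B64 = 44275.0 / 110592.0,
                    B65 = 253.0 / 4096.0;
static const double C1 = 37.0 / 378.0, C3 = 250.0 / 621.0, C4 = 125.0 / 594.0,
                    C6 = 512.0 / 1771.0;
static const double D1 = 2825.0 / 27648.0, D3 = 18575.0 / 48384.0,
                    D4 = 13525.0 / 55296.0, D5 = 277.0 / 14336.0,
                    D6 = 1.0 / 4.0;

// one Cash-Karp step over [t, t+h] with constant input r; returns error/scale
static inline double ck_step(double r, double inv_tmax, double q1, double q2,
                             double h, double rtol, double atol,
                             double &q1_out, double &q2_out) {
  double k11, k12, k21, k22, k31, k32, k41, k42, k51, k52, k61, k62;
  rhs(r, inv_tmax, q1, q2, k11, k12);
  rhs(r, inv_tmax, q1 + h * B21 * k11, q2 + h * B21 * k12, k21, k22);
  rhs(r, inv_tmax, q1 + h * (B31 * k11 + B32 * k21),
      q2 + h * (B31 * k12 + B32 * k22), k31, k32);
  rhs(r, inv_tmax, q1 + h * (B41 * k11 + B42 * k21 + B43 * k31),
      q2 + h * (B41 * k12 + B42 * k22 + B43 * k32), k41, k42);
  rhs(r, inv_tmax, q1 + h * (B51 * k11 + B52 * k21 + B53 * k31 + B54 * k41),
      q2 + h * (B51 * k12 + B52 * k22 + B53 * k32 + B54 * k42), k51, k52);
  rhs(r, inv_tmax,
      q1 + h * (B61 * k11 + B62 * k21 + B63 * k31 + B64 * k41 + B65 * k51),
      q2 + h * (B61 * k12 + B62 * k22 + B63 * k32 + B64 * k42 + B65 * k52),
      k61, k62);
  double y51 = q1 + h * (C1 * k11 + C3 * k31 + C4 * k41 + C6 * k61);
  double y52 = q2 + h * (C1 * k12 + C3 * k32 + C4 * k42 + C6 * k62);
  double y41 = q1 + h * (D1 * k11 + D3 * k31 + D4 * k41 + D5 * k51 + D6 * k61);
  double y42 = q2 + h * (D1 * k12 + D3 * k32 + D4 * k42 + D5 * k52 + D6 * k62);
  double e1 = std::fabs(y51 - y41), e2 = std::fabs(y52 - y42);
  double s1 = atol + rtol * std::max(std::fabs(q1), std::fabs(y51));
  double s2 = atol + rtol * std::max(std::fabs(q2), std::fabs(y52));
  double err = std::max(e1 / s1, e2 / s2);
  q1_out = y51;
  q2_out = y52;
  return err;
}

// adaptive integration over [t0, t1] with constant input r
static void integrate_segment(double r, double inv_tmax, double rtol,
                              double atol, double t0, double t1, double &q1,
                              double &q2, long &nstep, long &nreject) {
  double t = t0;
  double h = (t1 - t0);
  if (h <= 0.0) return;
  const double hmin = 1e-10 * std::max(1.0, t1);
  while (t < t1) {
    if (t + h > t1) h = t1 - t;
    double q1n, q2n;
    double err = ck_step(r, inv_tmax, q1, q2, h, rtol, atol, q1n, q2n);
    if (!std::isfinite(err) || !std::isfinite(q1n) || !std::isfinite(q2n))
      stop("integration failure: non-finite state");
    if (err <= 1.0) {
      t += h;
      q1 = q1n;
      q2 = q2n;
      nstep++;
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      nreject++;
      double fac = 0.9 * std::pow(err, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < hmin) stop("integration failure: step size underflow");
    }
  }
  if (q1 < 0.0 && q1 > -atol) q1 = 0.0;
  if (q2 < 0.0 && q2 > -atol) q2 = 0.0;
}

// piecewise-constant rate lookup: breaks (length m+1, sorted), rates (length m)
static inline double rate_at(const double t, const NumericVector &breaks,
                             const NumericVector &rates) {
  int m = rates.size();
  if (m == 0 || t < breaks[0] || t >= breaks[m]) return 0.0;
  // linear scan is fine: m is small (a handful of dose events per profile)
  for (int i = 0; i < m; i++)
    if (t >= breaks[i] && t < breaks[i + 1]) return rates[i];
  return 0.0;
}

// [[Rcpp::export]]
List ck_solve_cpp(NumericVector out_times, double tmax, NumericVector breaks,
                  NumericVector rates, double rtol, double atol) {
  if (tmax <= 0.0) stop("tmax must be positive");
  g_ode_calls++;
  int n = out_times.size();
  NumericVector q1_out(n), q2_out(n);
  double q1 = 0.0, q2 = 0.0, t = 0.0;
  double inv_tmax = 1.0 / tmax;
  long nstep = 0, nreject = 0;

  // merged, sorted event times: dosing breakpoints + requested output times
  std::vector<double> ev;
  for (int i = 0; i < breaks.size(); i++)
    if (breaks[i] > 0.0) ev.push_back(breaks[i]);
  for (int i = 0; i < n; i++) {
    if (out_times[i] < 0.0) stop("output times must be non-negative");
    if (i > 0 && out_times[i] < out_times[i - 1])
      stop("output times must be sorted");
    if (out_times[i] > 0.0) ev.push_back(out_times[i]);
  }
  std::sort(ev.begin(), ev.end());
  ev.erase(std::unique(ev.begin(), ev.end()), ev.end());

  int oi = 0;
  while (oi < n && out_times[oi] <= 0.0) {
    q1_out[oi] = 0.0;
    q2_out[oi] = 0.0;
    oi++;
  }
  for (size_t e = 0; e < ev.size(); e++) {
    double te = ev[e];
    double r = rate_at(0.5 * (t + te), breaks, rates);
    integrate_segment(r, inv_tmax, rtol, atol, t, te, q1, q2, nstep, nreject);
    t = te;
    while (oi < n && out_times[oi] <= t + 1e-12) {
      q1_out[oi] = q1;
      q2_out[oi] = q2;
      oi++;
    }
  }
  return List::create(_["Q1"] = q1_out, _["Q2"] = q2_out,
                      _["n_steps"] = (double) nstep,
                      _["n_reject"] = (double) nreject);
}

// ---------------------------------------------------------------------------
// profile likelihood and componentwise adaptive random-walk Metropolis
// ---------------------------------------------------------------------------

struct ProfileData {
  NumericVector y, times, breaks, rates;
  double wt, tend, conv, rtol, atol;
};

static std::vector<double> q2_at_times(const ProfileData &pd, double tmax) {
  List sol = ck_solve_cpp(pd.times, tmax, pd.breaks, pd.rates, pd.rtol,
                          pd.atol);
  NumericVector q2 = sol["Q2"];
  return std::vector<double>(q2.begin(), q2.end());
}

// log N(y; mu, kappa^2 + lam^2 mu^2) summed over observations
static double loglik_from_q2(const ProfileData &pd,
                             const std::vector<double> &q2, double tmax,
                             double mcr, double a, double b, double kappa,
                             double lam) {
  const double LOG2PI = 1.8378770664093454836;
  double scale = pd.conv / (tmax * pd.wt * mcr);
  double ll = 0.0;
  int n = pd.y.size();
  for (int m = 0; m < n; m++) {
    double mu = scale * q2[m] + a * (pd.times[m] - pd.tend) + b;
    double v = kappa * kappa + lam * lam * mu * mu;
    if (v <= 0.0) return R_NegInf;
    double res = pd.y[m] - mu;
    ll += -0.5 * (LOG2PI + std::log(v) + res * res / v);
  }
  return ll;
}

// [[Rcpp::export]]
double profile_loglik_cpp(NumericVector y, NumericVector times,
                          NumericVector breaks, NumericVector rates, double wt,
                          double tend, double conv, double tmax, double mcr,
                          double a, double b, double kappa, double lam,
                          double rtol, double atol) {
  ProfileData pd{y, times, breaks, rates, wt, tend, conv, rtol, atol};
  std::vector<double> q2 = q2_at_times(pd, tmax);
  return loglik_from_q2(pd, q2, tmax, mcr, a, b, kappa, lam);
}

static inline double sigmoid(double u) { return 1.0 / (1.0 + std::exp(-u)); }
static inline double logit(double p) { return std::log(p / (1.0 - p)); }

// parameter vector order: tmax, mcr, a, b, kappa, lam
// transformed scale: log(tmax), logit(mcr/0.25), a, b, logit(kappa/100),
// logit(lam)
struct Theta {
  double u[6];
  double tmax() const { return std::exp(u[0]); }
  double mcr() const { return 0.25 * sigmoid(u[1]); }
  double a() const { return u[2]; }
  double b() const { return u[3]; }
  double kappa() const { return 100.0 * sigmoid(u[4]); }
  double lam() const { return sigmoid(u[5]); }
};

// log prior density on the transformed scale (Jacobians included).
// pop = false: stage-1 flat priors
//   tmax ~ U(5,500), MCR ~ U(0,0.25), a,b ~ N(0,100^2),
//   kappa ~ U(0,100), lam ~ U(0,1)
// pop = true: population priors for theta
//   log tmax ~ N(eta1, sd1^2) truncated to (log 5, log 500),
//   log MCR ~ N(eta2, sd2^2) truncated to MCR < 0.25,
//   a ~ N(eta3, sd3^2), b ~ N(eta4, sd4^2); kappa, lam keep uniform priors
static double log_prior_u(const Theta &th, bool pop, const double *eta,
                          const double *sd) {
  double tmax = th.tmax();
  if (tmax <= 5.0 || tmax >= 500.0) return R_NegInf;
  double s2 = sigmoid(th.u[1]), s5 = sigmoid(th.u[4]), s6 = sigmoid(th.u[5]);
  if (s2 <= 0.0 || s2 >= 1.0 || s5 <= 0.0 || s5 >= 1.0 || s6 <= 0.0 ||
      s6 >= 1.0)
    return R_NegInf;
  double lp = 0.0;
  // kappa, lam: uniform on natural scale -> logistic Jacobians
  lp += std::log(s5) + std::log(1.0 - s5);
  lp += std::log(s6) + std::log(1.0 - s6);
  if (!pop) {
    lp += th.u[0];                                // U(5,500) on tmax
    lp += std::log(s2) + std::log(1.0 - s2);      // U(0,0.25) on MCR
    lp += R::dnorm(th.a(), 0.0, 100.0, 1);
    lp += R::dnorm(th.b(), 0.0, 100.0, 1);
  } else {
    lp += R::dnorm(th.u[0], eta[0], sd[0], 1);    // log tmax ~ N
    // log MCR ~ N: density wrt u2 is dnorm(log mcr) * (1 - mcr/0.25)
    double lmcr = std::log(th.mcr());
    lp += R::dnorm(lmcr, eta[1], sd[1], 1) + std::log(1.0 - s2);
    lp += R::dnorm(th.a(), eta[2], sd[2], 1);
    lp += R::dnorm(th.b(), eta[3], sd[3], 1);
  }
  return lp;
}

// One componentwise Metropolis sweep over the (up to) 6 parameters.
// Returns the updated state; accept[] records per-component acceptance.
static void metropolis_sweep(const ProfileData &pd, Theta &th,
                             std::vector<double> &q2, double &ll, double &lp,
                             const double *steps, bool pop, const double *eta,
                             const double *sd, bool fix_lam, int *accept) {
  for (int c = 0; c < 6; c++) {
    accept[c] = 0;
    if (c == 5 && fix_lam) continue;
    Theta prop = th;
    prop.u[c] = th.u[c] + steps[c] * R::norm_rand();
    double lp_new = log_prior_u(prop, pop, eta, sd);
    if (!std::isfinite(lp_new)) continue;
    std::vector<double> q2_new = q2;
    if (c == 0) q2_new = q2_at_times(pd, prop.tmax());
    double ll_new = loglik_from_q2(pd, q2_new, prop.tmax(), prop.mcr(),
                                   prop.a(), prop.b(), prop.kappa(),
                                   prop.lam());
    double lr = (ll_new + lp_new) - (ll + lp);
    if (std::log(R::unif_rand()) < lr) {
      th = prop;
      ll = ll_new;
      lp = lp_new;
      if (c == 0) q2 = q2_new;
      accept[c] = 1;
    }
  }
}

// Full stage-1 (or population-prior) chain. Adaptive scaling toward a 0.44
// per-component acceptance rate in batches of 50 during burn-in only, so the
// post-burn-in kernel satisfies detailed balance.
// [[Rcpp::export]]
List profile_chain_cpp(NumericVector y, NumericVector times,
                       NumericVector breaks, NumericVector rates, double wt,
                       double tend, double conv, NumericVector init,
                       int n_iter, int burn_in, int thin, bool pop,
                       NumericVector pop_eta, NumericVector pop_sd,
                       bool fix_lam, double rtol, double atol) {
  ProfileData pd{y, times, breaks, rates, wt, tend, conv, rtol, atol};
  Theta th;
  th.u[0] = std::log(init[0]);
  th.u[1] = logit(init[1] / 0.25);
  th.u[2] = init[2];
  th.u[3] = init[3];
  th.u[4] = logit(init[4] / 100.0);
  th.u[5] = logit(std::min(std::max(init[5], 1e-8), 1.0 - 1e-8));
  double eta[4] = {0, 0, 0, 0}, sd[4] = {1, 1, 1, 1};
  if (pop)
    for (int l = 0; l < 4; l++) { eta[l] = pop_eta[l]; sd[l] = pop_sd[l]; }

  std::vector<double> q2 = q2_at_times(pd, th.tmax());
  double lp = log_prior_u(th, pop, eta, sd);
  if (!std::isfinite(lp)) stop("initial state has zero prior density");
  double ll = loglik_from_q2(pd, q2, th.tmax(), th.mcr(), th.a(), th.b(),
                             th.kappa(), th.lam());
  if (!std::isfinite(ll)) stop("initial state has zero likelihood");

  double lsteps[6] = {std::log(0.1), std::log(0.2), std::log(0.05),
                      std::log(2.0), std::log(0.3), std::log(0.3)};
  double steps[6];
  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, 6);
  NumericVector acc_total(6);
  int acc_batch[6] = {0, 0, 0, 0, 0, 0};
  int accept[6];
  int batch = 0, kept = 0;

  for (int it = 1; it <= n_iter; it++) {
    for (int c = 0; c < 6; c++) steps[c] = std::exp(lsteps[c]);
    metropolis_sweep(pd, th, q2, ll, lp, steps, pop, eta, sd, fix_lam, accept);
    for (int c = 0; c < 6; c++) {
      acc_batch[c] += accept[c];
      if (it > burn_in) acc_total[c] += accept[c];
    }
    if (it <= burn_in && it % 50 == 0) {
      batch++;
      double delta = std::min(0.05, 1.0 / std::sqrt((double) batch));
      for (int c = 0; c < 6; c++) {
        lsteps[c] += (acc_batch[c] / 50.0 > 0.44) ? delta : -delta;
        acc_batch[c] = 0;
      }
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      draws(kept, 0) = th.tmax();
      draws(kept, 1) = th.mcr();
      draws(kept, 2) = th.a();
      draws(kept, 3) = th.b();
      draws(kept, 4) = th.kappa();
      draws(kept, 5) = th.lam();
      kept++;
    }
  }
  NumericVector final_steps(6);
  for (int c = 0; c < 6; c++) final_steps[c] = std::exp(lsteps[c]);
  return List::create(_["draws"] = draws,
                      _["acceptance"] = acc_total / (double) (n_iter - burn_in),
                      _["steps"] = final_steps);
}

// Single componentwise sweep for one profile under population priors, used by
// the direct (single-stage) joint sampler; step sizes are managed by the
// caller. state and steps are length 6 on the natural scale / transformed
// scale respectively.
// [[Rcpp::export]]
List profile_sweep_cpp(NumericVector y, NumericVector times,
                       NumericVector breaks, NumericVector rates, double wt,
                       double tend, double conv, NumericVector state,
                       NumericVector steps_in, NumericVector pop_eta,
                       NumericVector pop_sd, double rtol, double atol) {
  ProfileData pd{y, times, breaks, rates, wt, tend, conv, rtol, atol};
  Theta th;
  th.u[0] = std::log(state[0]);
  th.u[1] = logit(state[1] / 0.25);
  th.u[2] = state[2];
  th.u[3] = state[3];
  th.u[4] = logit(state[4] / 100.0);
  th.u[5] = logit(std::min(std::max(state[5], 1e-8), 1.0 - 1e-8));
  double eta[4], sd[4];
  for (int l = 0; l < 4; l++) { eta[l] = pop_eta[l]; sd[l] = pop_sd[l]; }
  std::vector<double> q2 = q2_at_times(pd, th.tmax());
  double lp = log_prior_u(th, true, eta, sd);
  double ll = loglik_from_q2(pd, q2, th.tmax(), th.mcr(), th.a(), th.b(),
                             th.kappa(), th.lam());
  double steps[6];
  for (int c = 0; c < 6; c++) steps[c] = steps_in[c];
  int accept[6];
  metropolis_sweep(pd, th, q2, ll, lp, steps, true, eta, sd, false, accept);
  NumericVector out(6), acc(6);
  out[0] = th.tmax();
  out[1] = th.mcr();
  out[2] = th.a();
  out[3] = th.b();
  out[4] = th.kappa();
  out[5] = th.lam();
  for (int c = 0; c < 6; c++) acc[c] = accept[c];
  return List::create(_["state"] = out, _["accept"] = acc);
}
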