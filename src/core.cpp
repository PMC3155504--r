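#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hill response functions, written to stay finite for arbitrarily large x
// (x^h overflows double for population bursts; the ratio form does not).
static inline double hill_up_c(double x, double k, double h) {
  if (x <= 0.0) return 0.0;
  double r = std::pow(k / x, h);
  return 1.0 / (1.0 + r);
}

static inline double hill_down_c(double x, double k, double h) {
  if (x <= 0.0) return 1.0;
  double r = std::pow(x / k, h);
  return 1.0 / (1.0 + r);
}

struct Pars {
  double delta, beta, eta, alpha_E, alpha_R, gamma_E, gamma_R, k_E, k_R, h;
  double d1, d2, a, r;
  double inflow_E, inflow_R; // constant resting-cell influx (reduced-model match)
};

// Right-hand side of the six-variable system:
// s = (E_r, R_r, E, R, l, L)
static inline void derivs(const double *s, const Pars &p, double *ds) {
  const double Er = s[0], Rr = s[1], E = s[2], R = s[3], l = s[4];
  const double huR = hill_up_c(R, p.k_R, p.h);
  const double hdR = hill_down_c(R, p.k_R, p.h);
  const double huE = hill_up_c(E, p.k_E, p.h);
  ds[0] = p.inflow_E - (p.delta + p.beta) * Er + p.eta * E;
  ds[1] = p.inflow_R - (p.delta + p.beta) * Rr + p.eta * R;
  ds[2] = p.delta * Er + p.alpha_E * E * hdR -
          p.gamma_E * E * (1.0 + huR) - p.eta * E;
  ds[3] = p.delta * Rr + p.alpha_R * R * huE - p.gamma_R * R - p.eta * R;
  double Eprime = (E / p.a) * (E / p.a); // second-order damage drive
  ds[4] = p.d1 * Eprime - (p.r + p.d2) * l;
  ds[5] = p.d2 * l;
}

static Pars unpack(const List &pars) {
  Pars p;
  p.delta = pars["delta"]; p.beta = pars["beta"]; p.eta = pars["eta"];
  p.alpha_E = pars["alpha_E"]; p.alpha_R = pars["alpha_R"];
  p.gamma_E = pars["gamma_E"]; p.gamma_R = pars["gamma_R"];
  p.k_E = pars["k_E"]; p.k_R = pars["k_R"]; p.h = pars["hill_h"];
  p.d1 = pars["d1"]; p.d2 = pars["d2"]; p.a = pars["a"]; p.r = pars["r"];
  p.inflow_E = pars["inflow_E"]; p.inflow_R = pars["inflow_R"];
  return p;
}

// Explicit fixed-step Euler with impulses realised as state jumps.
//
// imp_step: 0-based grid index at which each impulse lands (first grid point
//           at or after the impulse time); imp_pool: 0=E_r, 1=R_r, 2=E, 3=R;
//           imp_amount: cells added. Vectors must be sorted by imp_step.
// record_stride <= 0 disables trajectory recording (summary only).
// [[Rcpp::export]]
List euler_core(NumericVector state0, List pars,
                IntegerVector imp_step, IntegerVector imp_pool,
                NumericVector imp_amount,
                int n_steps, double dt, int record_stride) {
  if (state0.size() != 6) stop("state0 must have length 6");
  Pars p = unpack(pars);
  double s[6], ds[6];
  for (int i = 0; i < 6; ++i) s[i] = state0[i];

  const int n_imp = imp_step.size();
  int ii = 0;
  long clip_count = 0;
  double injected = 0.0;

  // impulses scheduled for the initial grid point
  while (ii < n_imp && imp_step[ii] <= 0) {
    s[imp_pool[ii]] += imp_amount[ii];
    injected += imp_amount[ii];
    ++ii;
  }

  int n_rec = (record_stride > 0) ? (n_steps / record_stride + 1) : 0;
  NumericMatrix rec(n_rec, 7);
  int ri = 0;
  if (record_stride > 0) {
    rec(ri, 0) = 0.0;
    for (int i = 0; i < 6; ++i) rec(ri, i + 1) = s[i];
    ++ri;
  }

  double peak_E = s[2], peak_R = s[3], sum_l = s[4];
  long n_sum = 1;

  for (int k = 1; k <= n_steps; ++k) {
    derivs(s, p, ds);
    for (int i = 0; i < 6; ++i) s[i] += dt * ds[i];
    while (ii < n_imp && imp_step[ii] == k) {
      s[imp_pool[ii]] += imp_amount[ii];
      injected += imp_amount[ii];
      ++ii;
    }
    for (int i = 0; i < 6; ++i) {
      if (s[i] < 0.0) { s[i] = 0.0; ++clip_count; }
      if (!std::isfinite(s[i])) {
        stop("non-finite state at step %d (t = %g days), component %d",
             k, k * dt, i + 1);
      }
    }
    if (s[2] > peak_E) peak_E = s[2];
    if (s[3] > peak_R) peak_R = s[3];
    sum_l += s[4];
    ++n_sum;
    if (record_stride > 0 && k % record_stride == 0) {
      rec(ri, 0) = k * dt;
      for (int i = 0; i < 6; ++i) rec(ri, i + 1) = s[i];
      ++ri;
    }
  }

  NumericVector fin(6);
  for (int i = 0; i < 6; ++i) fin[i] = s[i];
  return List::create(
    _["record"] = rec, _["final_state"] = fin,
    _["peak_E"] = peak_E, _["peak_R"] = peak_R,
    _["mean_l"] = sum_l / n_sum,
    _["n_clips"] = (double)clip_count, _["injected"] = injected,
    _["n_impulses_applied"] = ii);
}

// Reduced two-variable system (activated pools only, constant expected
// inflow): dE = L_E + aE*E*hd(R) - gE*E*(1+hu(R)) - eta*E,
//          dR = L_R + aR*R*hu(E) - gR*R - eta*R.
// [[Rcpp::export]]
NumericVector reduced_rates_core(double E, double R, List pars,
                                 double lambda_E, double lambda_R) {
  Pars p = unpack(pars);
  NumericVector out(2);
  out[0] = lambda_E + p.alpha_E * E * hill_down_c(R, p.k_R, p.h) -
           p.gamma_E * E * (1.0 + hill_up_c(R, p.k_R, p.h)) - p.eta * E;
  out[1] = lambda_R + p.alpha_R * R * hill_up_c(E, p.k_E, p.h) -
           p.gamma_R * R - p.eta * R;
  return out;
}

// [[Rcpp::export]]
NumericMatrix reduced_euler_core(double E0, double R0, List pars,
                                 double lambda_E, double lambda_R,
                                 int n_steps, double dt, int record_stride) {
  Pars p = unpack(pars);
  double E = E0, R = R0;
  int n_rec = n_steps / record_stride + 1;
  NumericMatrix rec(n_rec, 3);
  int ri = 0;
  rec(ri, 0) = 0.0; rec(ri, 1) = R; rec(ri, 2) = E; ++ri;
  for (int k = 1; k <= n_steps; ++k) {
    double dE = lambda_E + p.alpha_E * E * hill_down_c(R, p.k_R, p.h) -
                p.gamma_E * E * (1.0 + hill_up_c(R, p.k_R, p.h)) - p.eta * E;
    double dR = lambda_R + p.alpha_R * R * hill_up_c(E, p.k_E, p.h) -
                p.gamma_R * R - p.eta * R;
    E += dt * dE; R += dt * dR;
    if (E < 0.0) E = 0.0;
    if (R < 0.0) R = 0.0;
    if (!std::isfinite(E) || !std::isfinite(R))
      stop("non-finite reduced state at step %d (t = %g days)", k, k * dt);
    if (k % record_stride == 0) {
      rec(ri, 0) = k * dt; rec(ri, 1) = R; rec(ri, 2) = E; ++ri;
    }
  }
  return rec;
}
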