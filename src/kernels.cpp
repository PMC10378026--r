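#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 0! .. 8!
static const int FACT[9] = {1, 1, 2, 6, 24, 120, 720, 5040, 40320};

// Lexicographic (Lehmer) index of the stable rank pattern of the window
// starting at i with spacing tau.  Stable ranking: for j > i, x[j] outranks
// x[i] on exact ties, so only strict "<" comparisons are needed.
static inline int pattern_index_at(const double *x, int i, int D, int tau) {
  int idx = 0;
  for (int p = 0; p < D - 1; ++p) {
    const double xp = x[i + p * tau];
    int smaller = 0;
    for (int q = p + 1; q < D; ++q)
      if (x[i + q * tau] < xp) ++smaller;
    idx += smaller * FACT[D - 1 - p];
  }
  return idx;
}

// [[Rcpp::export]]
IntegerVector symbolize_cpp(NumericVector x, int D, int tau) {
  const int n = x.size() - (D - 1) * tau;
  IntegerVector out(n);
  const double *px = x.begin();
  for (int i = 0; i < n; ++i) out[i] = pattern_index_at(px, i, D, tau);
  return out;
}

// [[Rcpp::export]]
IntegerVector ordinal_counts_cpp(NumericVector x, int D, int tau) {
  const int n = x.size() - (D - 1) * tau;
  IntegerVector counts(FACT[D]);
  const double *px = x.begin();
  for (int i = 0; i < n; ++i) ++counts[pattern_index_at(px, i, D, tau)];
  return counts;
}

static double entropy_nats(const std::vector<int> &counts, double n) {
  double h = 0.0;
  for (size_t k = 0; k < counts.size(); ++k) {
    if (counts[k] > 0) {
      const double p = counts[k] / n;
      h -= p * std::log(p);
    }
  }
  return h;
}

// PE (nats) for every tau in 1..tau_max
// [[Rcpp::export]]
NumericVector pe_curve_cpp(NumericVector x, int D, int tau_max) {
  NumericVector pe(tau_max);
  const double *px = x.begin();
  const int nfact = FACT[D];
  std::vector<int> counts(nfact);
  for (int tau = 1; tau <= tau_max; ++tau) {
    const int n = x.size() - (D - 1) * tau;
    std::fill(counts.begin(), counts.end(), 0);
    for (int i = 0; i < n; ++i) ++counts[pattern_index_at(px, i, D, tau)];
    pe[tau - 1] = entropy_nats(counts, (double)n);
  }
  return pe;
}

// Leaky integrate-and-fire Euler integration.
// Units: membrane potential mV, dt and tau_m ms, R MOhm, I nA (R*I in mV).
// I is the full per-sample input current; randomness is drawn in R.
// V[0] = v_rest; at each step, if the updated potential reaches v_th the
// (suprathreshold) value is recorded, the sample index is logged as a spike
// and the state resets to v_reset.
// [[Rcpp::export]]
List iaf_simulate_cpp(NumericVector I, double dt, double v_rest,
                      double v_reset, double v_th, double R, double tau_m) {
  const int n = I.size();
  NumericVector V(n);
  std::vector<int> spikes;
  double v = v_rest;
  V[0] = v;
  for (int t = 1; t < n; ++t) {
    v += dt / tau_m * (-(v - v_rest) + R * I[t - 1]);
    V[t] = v;
    if (v >= v_th) {
      spikes.push_back(t);  // 0-based sample index
      v = v_reset;
    }
  }
  return List::create(_["V"] = V, _["spike_idx"] = wrap(spikes));
}

// Mackey-Glass Euler integration with delay tau_s in integration steps and
// constant pre-history x0.  Returns the trajectory; sets the "diverged"
// attribute if |x| exceeds 1e6 (integration stops there).
// [[Rcpp::export]]
NumericVector mg_simulate_cpp(int n, double dt, double a, double c,
                              int tau_s, double x0) {
  NumericVector x(n);
  x[0] = x0;
  bool diverged = false;
  for (int t = 1; t < n; ++t) {
    const int d = t - 1 - tau_s;
    const double xd = (d >= 0) ? x[d] : x0;
    const double fb = a * xd / (1.0 + std::pow(xd, c));
    x[t] = x[t - 1] + dt * (-x[t - 1] + fb);
    if (!std::isfinite(x[t]) || std::fabs(x[t]) > 1e6) {
      diverged = true;
      for (int k = t; k < n; ++k) x[k] = NA_REAL;
      break;
    }
  }
  x.attr("diverged") = diverged;
  return x;
}
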