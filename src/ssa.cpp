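// Stochastic simulation core: Gillespie's direct method and a hybrid
// exact/tau-leap scheme over a small typed reaction network.
//
// Species counts are carried as doubles holding integer values so that
// copy numbers up to ~1e15 (far beyond the ~1e7 xanthosine counts of
// the high-expression state) are represented exactly.
//
// Reaction propensity types:
//   0 constant:   a = rate
//   1 linear:     a = rate * n[scale_sp]
//   2 mm:         a = rate * (n[mm_sp]/omega) / (mm_K + n[mm_sp]/omega)
//                     * (scale_sp >= 0 ? n[scale_sp] : 1)
//   3 regulated:  a = rate * p_active(n[mm_sp]/omega)   (transcription)
//
// The regulated type evaluates the MWC active fraction and the
// thermodynamic promoter-activity formula on the concentration-converted
// count; the continuous regulatory functions are kept as-is rather than
// discretized.
//
// Optional geometric bursts: a reaction with burst_mean > 1 produces,
// per firing, 1 + NegBinomial extra copies of its (single, +1) product,
// i.e. a geometric burst on {1, 2, ...} with the given mean.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct RegParams {
  double K_chiA, K_IA, deps_x, XapR_R, deps_coop;
  int inducer_sites, promoter_sites, policy; // policy 0 = fully occupied, 1 = any bound
};

static inline double p_active(double x, const RegParams &rp) {
  double u = x / rp.K_chiA;
  double act, inact;
  if (rp.inducer_sites == 2) {
    act = (1.0 + u) * (1.0 + u);
    double v = 1.0 + u / rp.K_IA;
    inact = std::exp(rp.deps_x) * v * v;
  } else {
    act = 1.0 + u;
    inact = std::exp(rp.deps_x) * (1.0 + u / rp.K_IA);
  }
  double r = rp.XapR_R * act / (act + inact);
  if (rp.promoter_sites == 1) return r / (1.0 + r);
  double E = std::exp(rp.deps_coop);
  double z = 1.0 + 2.0 * r + r * r * E;
  if (rp.policy == 1) return (2.0 * r + r * r * E) / z;
  return r * r * E / z;
}

static inline double propensity(int type, double rate, int scale_sp,
                                int mm_sp, double mm_K, double omega,
                                const std::vector<double> &n,
                                const RegParams &rp) {
  switch (type) {
  case 0: return rate;
  case 1: return rate * n[scale_sp];
  case 2: {
    double x = n[mm_sp] / omega;
    double f = x / (mm_K + x);
    return rate * f * (scale_sp >= 0 ? n[scale_sp] : 1.0);
  }
  case 3: return rate * p_active(n[mm_sp] / omega, rp);
  }
  return 0.0;
}

// geometric burst size on {1, 2, ...} with mean b (b >= 1)
static inline double burst_size(double b) {
  if (b <= 1.0) return 1.0;
  return 1.0 + R::rgeom(1.0 / b);
}

static RegParams unpack_reg(const NumericVector &reg) {
  RegParams rp;
  rp.K_chiA = reg[0]; rp.K_IA = reg[1]; rp.deps_x = reg[2];
  rp.XapR_R = reg[3]; rp.deps_coop = reg[4];
  rp.inducer_sites = (int)reg[5]; rp.promoter_sites = (int)reg[6];
  rp.policy = (int)reg[7];
  return rp;
}

// record all sample times in [t_prev, t_next) with the current state
static inline void record_upto(double t_next, const NumericVector &rec_times,
                               NumericMatrix &rec_states, int &rec_idx,
                               const std::vector<double> &n) {
  int S = n.size();
  while (rec_idx < rec_times.size() && rec_times[rec_idx] < t_next) {
    for (int s = 0; s < S; ++s) rec_states(rec_idx, s) = n[s];
    ++rec_idx;
  }
}

// [[Rcpp::export]]
List ssa_direct_cpp(IntegerMatrix stoich, IntegerVector type,
                    NumericVector rate, IntegerVector scale_sp,
                    IntegerVector mm_sp, NumericVector mm_K,
                    NumericVector burst_mean, IntegerVector burst_sp,
                    NumericVector reg, double omega,
                    NumericVector init, double t_end,
                    NumericVector rec_times, double max_events,
                    int monitor_sp, double monitor_val) {
  const int S = stoich.nrow(), R_n = stoich.ncol();
  RegParams rp = unpack_reg(reg);
  std::vector<double> n(init.begin(), init.end());
  std::vector<double> a(R_n);
  double t = 0.0, n_events = 0.0, first_passage = NA_REAL;
  int status = 0, rec_idx = 0;
  NumericMatrix rec_states(rec_times.size(), S);
  if (monitor_sp >= 0 && n[monitor_sp] >= monitor_val) first_passage = 0.0;

  while (t < t_end) {
    double a0 = 0.0;
    for (int j = 0; j < R_n; ++j) {
      a[j] = propensity(type[j], rate[j], scale_sp[j], mm_sp[j], mm_K[j],
                        omega, n, rp);
      if (a[j] < 0.0 || !std::isfinite(a[j])) { status = 2; break; }
      a0 += a[j];
    }
    if (status == 2) break;
    if (a0 <= 0.0) { t = t_end; break; }
    double dt = R::rexp(1.0 / a0);
    double t_next = t + dt;
    if (t_next > t_end) { t = t_end; break; }
    record_upto(t_next, rec_times, rec_states, rec_idx, n);
    // choose reaction
    double u = R::runif(0.0, 1.0) * a0, acc = 0.0;
    int j = R_n - 1;
    for (int k = 0; k < R_n; ++k) { acc += a[k]; if (u <= acc) { j = k; break; } }
    double extra = 0.0;
    if (burst_mean[j] > 1.0) extra = burst_size(burst_mean[j]) - 1.0;
    for (int s = 0; s < S; ++s) n[s] += stoich(s, j);
    if (extra > 0.0 && burst_sp[j] >= 0) n[burst_sp[j]] += extra;
    t = t_next;
    if (monitor_sp >= 0 && !std::isfinite(first_passage) &&
        n[monitor_sp] >= monitor_val) first_passage = t;
    if (++n_events >= max_events) { status = 1; break; }
  }
  record_upto(t + 1e-300, rec_times, rec_states, rec_idx, n);
  // remaining sample times (at or beyond the horizon) get the final state
  while (rec_idx < rec_times.size()) {
    for (int s = 0; s < S; ++s) rec_states(rec_idx, s) = n[s];
    ++rec_idx;
  }
  return List::create(_["final"] = NumericVector(n.begin(), n.end()),
                      _["t_final"] = t, _["n_events"] = n_events,
                      _["status"] = status, _["states"] = rec_states,
                      _["first_passage"] = first_passage);
}

// [[Rcpp::export]]
List ssa_hybrid_cpp(IntegerMatrix stoich, IntegerVector type,
                    NumericVector rate, IntegerVector scale_sp,
                    IntegerVector mm_sp, NumericVector mm_K,
                    NumericVector burst_mean, IntegerVector burst_sp,
                    NumericVector reg, double omega,
                    NumericVector init, double t_end,
                    NumericVector rec_times, double max_steps,
                    double eps, double count_thresh, double rate_thresh,
                    int monitor_sp, double monitor_val) {
  const int S = stoich.nrow(), R_n = stoich.ncol();
  RegParams rp = unpack_reg(reg);
  std::vector<double> n(init.begin(), init.end());
  std::vector<double> a(R_n), mu(S), var(S), delta(S);
  std::vector<bool> leap(R_n);
  double t = 0.0, n_steps = 0.0, first_passage = NA_REAL;
  int status = 0, rec_idx = 0;
  NumericMatrix rec_states(rec_times.size(), S);
  if (monitor_sp >= 0 && n[monitor_sp] >= monitor_val) first_passage = 0.0;

  while (t < t_end) {
    if (++n_steps > max_steps) { status = 1; break; }
    double a0 = 0.0, a_slow = 0.0;
    bool any_leap = false;
    for (int j = 0; j < R_n; ++j) {
      a[j] = propensity(type[j], rate[j], scale_sp[j], mm_sp[j], mm_K[j],
                        omega, n, rp);
      if (a[j] < 0.0 || !std::isfinite(a[j])) { status = 2; break; }
      a0 += a[j];
      // a channel is tau-leapable when every species it changes is
      // abundant and its propensity is high; otherwise it is exact
      bool lp = a[j] >= rate_thresh;
      if (lp) {
        for (int s = 0; s < S; ++s)
          if (stoich(s, j) != 0 && n[s] < count_thresh) { lp = false; break; }
      }
      leap[j] = lp;
      if (lp) any_leap = true; else a_slow += a[j];
    }
    if (status == 2) break;
    if (a0 <= 0.0) { t = t_end; break; }

    if (!any_leap) {
      // pure exact step
      double dt = R::rexp(1.0 / a_slow);
      double t_next = t + dt;
      if (t_next > t_end) { t = t_end; break; }
      record_upto(t_next, rec_times, rec_states, rec_idx, n);
      double u = R::runif(0.0, 1.0) * a_slow, acc = 0.0;
      int j = -1;
      for (int k = 0; k < R_n; ++k) {
        if (leap[k]) continue;
        acc += a[k];
        if (u <= acc) { j = k; break; }
      }
      if (j < 0) for (int k = R_n - 1; k >= 0; --k) if (!leap[k]) { j = k; break; }
      double extra = (burst_mean[j] > 1.0) ? burst_size(burst_mean[j]) - 1.0 : 0.0;
      for (int s = 0; s < S; ++s) n[s] += stoich(s, j);
      if (extra > 0.0 && burst_sp[j] >= 0) n[burst_sp[j]] += extra;
      t = t_next;
    } else {
      // leap-size selection: bounded relative change of the species
      // affected by the leapable channels
      for (int s = 0; s < S; ++s) { mu[s] = 0.0; var[s] = 0.0; }
      for (int j = 0; j < R_n; ++j) {
        if (!leap[j]) continue;
        for (int s = 0; s < S; ++s) {
          int v = stoich(s, j);
          if (v != 0) { mu[s] += v * a[j]; var[s] += (double)v * v * a[j]; }
        }
      }
      double tau_leap = t_end - t;
      for (int s = 0; s < S; ++s) {
        if (mu[s] == 0.0 && var[s] == 0.0) continue;
        double bound = std::max(eps * n[s], 1.0);
        if (mu[s] != 0.0) tau_leap = std::min(tau_leap, bound / std::fabs(mu[s]));
        if (var[s] > 0.0) tau_leap = std::min(tau_leap, bound * bound / var[s]);
      }
      double t_slow = (a_slow > 0.0) ? R::rexp(1.0 / a_slow) : R_PosInf;
      double tau_try = std::min(tau_leap, t_slow);
      if (tau_try > t_end - t) tau_try = t_end - t;
      bool ok = false;
      int halvings = 0;
      while (!ok) {
        for (int s = 0; s < S; ++s) delta[s] = 0.0;
        for (int j = 0; j < R_n; ++j) {
          if (!leap[j]) continue;
          double k = R::rpois(a[j] * tau_try);
          if (k > 0.0) {
            double prod = k;
            if (burst_mean[j] > 1.0) {
              double b = burst_mean[j];
              prod = k + R::rnbinom(k, 1.0 / b);
            }
            for (int s = 0; s < S; ++s) {
              int v = stoich(s, j);
              if (v != 0) {
                // bursts only inflate the (+1) product species
                if (v > 0 && s == burst_sp[j]) delta[s] += prod;
                else delta[s] += v * k;
              }
            }
          }
        }
        ok = true;
        for (int s = 0; s < S; ++s)
          if (n[s] + delta[s] < 0.0) { ok = false; break; }
        if (!ok) {
          tau_try *= 0.5;
          if (++halvings > 60) { status = 3; break; } // tau underflow
        }
      }
      if (status == 3) break;
      bool fire_slow = (t_slow <= tau_try);
      double t_next = t + tau_try;
      record_upto(t_next, rec_times, rec_states, rec_idx, n);
      for (int s = 0; s < S; ++s) n[s] += delta[s];
      if (fire_slow && a_slow > 0.0) {
        double u = R::runif(0.0, 1.0) * a_slow, acc = 0.0;
        int j = -1;
        for (int k = 0; k < R_n; ++k) {
          if (leap[k]) continue;
          acc += a[k];
          if (u <= acc) { j = k; break; }
        }
        if (j < 0) for (int k = R_n - 1; k >= 0; --k) if (!leap[k]) { j = k; break; }
        double extra = (burst_mean[j] > 1.0) ? burst_size(burst_mean[j]) - 1.0 : 0.0;
        bool neg = false;
        for (int s = 0; s < S; ++s)
          if (n[s] + stoich(s, j) < 0.0) { neg = true; break; }
        if (!neg) {
          for (int s = 0; s < S; ++s) n[s] += stoich(s, j);
          if (extra > 0.0 && burst_sp[j] >= 0) n[burst_sp[j]] += extra;
        }
      }
      t = t_next;
    }
    if (monitor_sp >= 0 && !std::isfinite(first_passage) &&
        n[monitor_sp] >= monitor_val) first_passage = t;
  }
  record_upto(t + 1e-300, rec_times, rec_states, rec_idx, n);
  while (rec_idx < rec_times.size()) {
    for (int s = 0; s < S; ++s) rec_states(rec_idx, s) = n[s];
    ++rec_idx;
  }
  return List::create(_["final"] = NumericVector(n.begin(), n.end()),
                      _["t_final"] = t, _["n_events"] = n_steps,
                      _["status"] = status, _["states"] = rec_states,
                      _["first_passage"] = first_passage);
}
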