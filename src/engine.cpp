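#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// splitmix64: derives a well-mixed 64-bit stream seed per patient
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// xoshiro256++ gives each patient an independent, platform-stable stream
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) { seed = splitmix64(seed); s[i] = seed; }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// Flattened per-cycle transition probabilities, cycle-major so each cycle's
// transitions are contiguous: P[k * n_tr + t] = cp(k, rate[t]) * frac[fr[t]].
static std::vector<double> flatten_probs(const NumericMatrix& cp,
                                         const IntegerVector& tr_rate,
                                         const IntegerVector& tr_frac,
                                         const NumericVector& frac) {
  const int n_cycles = cp.nrow();
  const int n_tr = tr_rate.size();
  std::vector<double> P((size_t)n_cycles * n_tr);
  std::vector<double> row(cp.ncol());
  for (int k = 0; k < n_cycles; ++k) {
    for (int c = 0; c < cp.ncol(); ++c) row[c] = cp(k, c);
    double* pk = &P[(size_t)k * n_tr];
    for (int t = 0; t < n_tr; ++t) {
      const double p = row[tr_rate[t] - 1] * frac[tr_frac[t] - 1];
      if (p < 0.0 || p > 1.0)
        stop("transition probability %f outside [0,1] at cycle %d", p, k);
      pk[t] = p;
    }
  }
  return P;
}

// [[Rcpp::export]]
List cohort_run_cpp(int n_states, int dead_state, int start_state,
                    IntegerVector tr_from, IntegerVector tr_to,
                    IntegerVector tr_rate, IntegerVector tr_frac,
                    IntegerVector tr_event,
                    NumericMatrix cp, NumericVector frac,
                    NumericVector event_cost, NumericVector event_du,
                    NumericVector state_cost, NumericVector state_util,
                    double cycle_days, double disc_rate,
                    bool half_cycle, bool full_trace) {
  const int n_cycles = cp.nrow();
  const int n_tr = tr_from.size();
  const double dt_yr = cycle_days / 365.25;

  std::vector<double> P = flatten_probs(cp, tr_rate, tr_frac, frac);
  std::vector<int> from(n_tr), to(n_tr), ev(n_tr);
  for (int t = 0; t < n_tr; ++t) {
    from[t] = tr_from[t] - 1; to[t] = tr_to[t] - 1; ev[t] = tr_event[t] - 1;
  }
  std::vector<double> ecost(event_cost.begin(), event_cost.end());
  std::vector<double> edu(event_du.begin(), event_du.end());
  std::vector<double> scost(state_cost.begin(), state_cost.end());
  std::vector<double> sutil(state_util.begin(), state_util.end());

  std::vector<double> occ(n_states, 0.0), nocc(n_states, 0.0),
      outp(n_states, 0.0);
  occ[start_state - 1] = 1.0;

  double cost = 0, qaly = 0, ly = 0, cost_d = 0, qaly_d = 0, ly_d = 0;

  NumericMatrix occ_trace;
  NumericMatrix inc_trace;  // cost, qaly, ly and discounted twins per cycle
  if (full_trace) {
    occ_trace = NumericMatrix(n_cycles + 1, n_states);
    inc_trace = NumericMatrix(n_cycles, 6);
    for (int s = 0; s < n_states; ++s) occ_trace(0, s) = occ[s];
  }

  for (int k = 0; k < n_cycles; ++k) {
    const double df = std::pow(1.0 + disc_rate, -k * dt_yr);
    const double* pk = &P[(size_t)k * n_tr];

    std::fill(nocc.begin(), nocc.end(), 0.0);
    std::fill(outp.begin(), outp.end(), 0.0);
    double ev_cost = 0.0, ev_du_qaly = 0.0;
    for (int t = 0; t < n_tr; ++t) {
      const double o = occ[from[t]];
      if (o <= 0.0) continue;
      const double p = pk[t];
      outp[from[t]] += p;
      nocc[to[t]] += o * p;
      ev_cost += o * p * ecost[ev[t]];
      if (edu[ev[t]] != 0.0) {
        const double u0 = sutil[from[t]];
        ev_du_qaly += o * p * (clamp01(u0 + edu[ev[t]]) - u0);
      }
    }
    for (int s = 0; s < n_states; ++s) {
      if (s == dead_state - 1) { nocc[s] += occ[s]; continue; }
      const double rem = 1.0 - outp[s];
      if (rem < -1e-12)
        stop("event probabilities for state %d sum to %f > 1 at cycle %d",
             s + 1, outp[s], k);
      nocc[s] += occ[s] * (rem < 0 ? 0 : rem);
    }

    // membership rewards; the optional half-cycle correction averages the
    // start- and end-of-cycle occupancy for state (not event) rewards
    double c_cost = 0, c_util = 0, c_alive = 0;
    for (int s = 0; s < n_states; ++s) {
      const double w = half_cycle ? 0.5 * (occ[s] + nocc[s]) : occ[s];
      c_cost += w * scost[s];
      c_util += w * sutil[s];
      if (s != dead_state - 1) c_alive += w;
    }
    const double cyc_cost = c_cost + ev_cost;
    const double cyc_qaly = (c_util + ev_du_qaly) * dt_yr;
    const double cyc_ly = c_alive * dt_yr;

    cost += cyc_cost;   qaly += cyc_qaly;   ly += cyc_ly;
    cost_d += cyc_cost * df; qaly_d += cyc_qaly * df; ly_d += cyc_ly * df;

    if (full_trace) {
      inc_trace(k, 0) = cyc_cost; inc_trace(k, 1) = cyc_qaly;
      inc_trace(k, 2) = cyc_ly;   inc_trace(k, 3) = cyc_cost * df;
      inc_trace(k, 4) = cyc_qaly * df; inc_trace(k, 5) = cyc_ly * df;
    }
    occ.swap(nocc);
    if (full_trace)
      for (int s = 0; s < n_states; ++s) occ_trace(k + 1, s) = occ[s];
  }

  NumericVector totals = NumericVector::create(
    _["cost"] = cost, _["qaly"] = qaly, _["ly"] = ly,
    _["cost_disc"] = cost_d, _["qaly_disc"] = qaly_d, _["ly_disc"] = ly_d);
  if (!full_trace) return List::create(_["totals"] = totals);
  return List::create(_["totals"] = totals, _["occupancy"] = occ_trace,
                      _["increments"] = inc_trace);
}

// [[Rcpp::export]]
List microsim_cpp(int n_states, int dead_state, int start_state,
                  IntegerVector tr_from, IntegerVector tr_to,
                  IntegerVector tr_rate, IntegerVector tr_frac,
                  IntegerVector tr_event,
                  NumericMatrix cp, NumericVector frac,
                  NumericVector event_cost, NumericVector event_du,
                  NumericVector state_cost, NumericVector state_util,
                  double cycle_days, double disc_rate,
                  int n_patients, double master_seed, bool log_events) {
  const int n_cycles = cp.nrow();
  const int n_tr = tr_from.size();
  const double dt_yr = cycle_days / 365.25;

  // CSR over transitions (tr_from must be sorted ascending)
  std::vector<int> row_ptr(n_states + 1, 0);
  for (int t = 0; t < n_tr; ++t) row_ptr[tr_from[t]]++;
  for (int s = 0; s < n_states; ++s) row_ptr[s + 1] += row_ptr[s];
  for (int t = 1; t < n_tr; ++t)
    if (tr_from[t] < tr_from[t - 1]) stop("transitions must be sorted by source");

  std::vector<double> P = flatten_probs(cp, tr_rate, tr_frac, frac);
  std::vector<int> to(n_tr), ev(n_tr);
  for (int t = 0; t < n_tr; ++t) { to[t] = tr_to[t] - 1; ev[t] = tr_event[t] - 1; }
  std::vector<double> ecost(event_cost.begin(), event_cost.end());
  std::vector<double> edu(event_du.begin(), event_du.end());
  std::vector<double> scost(state_cost.begin(), state_cost.end());
  std::vector<double> sutil(state_util.begin(), state_util.end());

  std::vector<double> dfs(n_cycles);
  for (int k = 0; k < n_cycles; ++k)
    dfs[k] = std::pow(1.0 + disc_rate, -k * dt_yr);

  NumericMatrix totals(n_patients, 6);
  std::vector<int> log_pat, log_cycle, log_state, log_event, log_to;
  std::vector<double> log_cost, log_util;

  const uint64_t ms = (uint64_t)master_seed;
  for (int i = 0; i < n_patients; ++i) {
    Xoshiro rng(splitmix64(ms ^ (uint64_t)(i + 1) * 0x5851F42D4C957F2DULL));
    int s = start_state - 1;
    double cost = 0, qaly = 0, ly = 0, cost_d = 0, qaly_d = 0, ly_d = 0;
    for (int k = 0; k < n_cycles && s != dead_state - 1; ++k) {
      const double* pk = &P[(size_t)k * n_tr];
      double c = scost[s];
      double u = sutil[s];
      int e = 0;        // 0 = no event
      int nxt = s;
      const double r = rng.unif();
      double cum = 0.0;
      for (int t = row_ptr[s]; t < row_ptr[s + 1]; ++t) {
        cum += pk[t];
        if (r < cum) {
          e = ev[t] + 1;
          nxt = to[t];
          c += ecost[ev[t]];
          u = clamp01(u + edu[ev[t]]);
          break;
        }
      }
      if (cum > 1.0 + 1e-12)
        stop("event probabilities sum to %f > 1 for state %d", cum, s + 1);
      const double df = dfs[k];
      cost += c; qaly += u * dt_yr; ly += dt_yr;
      cost_d += c * df; qaly_d += u * dt_yr * df; ly_d += dt_yr * df;
      if (log_events) {
        log_pat.push_back(i + 1); log_cycle.push_back(k);
        log_state.push_back(s + 1); log_event.push_back(e);
        log_to.push_back(nxt + 1);
        log_cost.push_back(c); log_util.push_back(u);
      }
      s = nxt;
    }
    totals(i, 0) = cost; totals(i, 1) = qaly; totals(i, 2) = ly;
    totals(i, 3) = cost_d; totals(i, 4) = qaly_d; totals(i, 5) = ly_d;
  }

  List out = List::create(_["totals"] = totals);
  if (log_events) {
    out["log"] = List::create(
      _["patient"] = wrap(log_pat), _["cycle"] = wrap(log_cycle),
      _["state"] = wrap(log_state), _["event"] = wrap(log_event),
      _["to_state"] = wrap(log_to), _["cost_increment"] = wrap(log_cost),
      _["utility"] = wrap(log_util));
  }
  return out;
}
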