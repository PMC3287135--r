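#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Self-contained, platform-independent RNG: splitmix64 (seed expansion and
// seed derivation) + xoshiro256++ (stream).  Using our own generator rather
// than R's keeps trajectories bit-reproducible across platforms and lets
// per-run seeds be derived independently of execution order.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1): 53-bit mantissa, zero excluded so log() is safe
  inline double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    while (u <= 0.0) u = (next() >> 11) * 0x1.0p-53;
    return u;
  }
};

// [[Rcpp::export(name = ".derive_seed_cpp")]]
double derive_seed_cpp(double base_seed, double index, double stream) {
  // hash (base_seed, index, stream) -> 53-bit integer, order-independent
  uint64_t x = (uint64_t)(int64_t)base_seed;
  x ^= 0xA24BAED4963EE407ULL;
  (void)splitmix64_next(x);
  x ^= (uint64_t)(int64_t)index;
  (void)splitmix64_next(x);
  x ^= (uint64_t)(int64_t)stream;
  uint64_t h = splitmix64_next(x);
  return (double)(h >> 11);  // < 2^53, exactly representable
}

// ---------------------------------------------------------------------------
// Mass-action propensities.  Reaction j has reactant indices/multiplicities,
// modifier indices (propensity factor = plain count) and rate constant k.
// Propensity = k * prod_i [ n_i (n_i-1) ... (n_i-m_i+1) / m_i! ] * prod_mod n.
// ---------------------------------------------------------------------------

struct MAReaction {
  double k;
  std::vector<int> ridx;   // reactant species indices (0-based)
  std::vector<int> rmult;  // multiplicities
  std::vector<int> midx;   // modifier species indices
};

static inline double falling_factorial_over_fact(double n, int m) {
  double v = 1.0, f = 1.0;
  for (int i = 0; i < m; ++i) { v *= (n - i); f *= (i + 1); }
  if (v < 0.0) v = 0.0;  // counts below multiplicity cannot fire
  return v / f;
}

static inline double ma_propensity(const MAReaction &r,
                                   const std::vector<double> &x) {
  double a = r.k;
  for (size_t i = 0; i < r.ridx.size(); ++i)
    a *= falling_factorial_over_fact(x[r.ridx[i]], r.rmult[i]);
  for (size_t i = 0; i < r.midx.size(); ++i)
    a *= x[r.midx[i]];
  return a;
}

// ---------------------------------------------------------------------------
// Gillespie direct method with dependency-graph propensity updates: after a
// firing only the propensities of reactions that involve a changed species
// are recomputed, and the running total is refreshed from scratch
// periodically to cancel floating-point drift.
//   mode 0: elemental — channels are the reactions themselves.
//   mode 1: quasi-deterministic — per-species +1/-1 channels with
//           propensities max(drift_i, 0) and max(-drift_i, 0), where
//           drift_i = sum_j S[i,j] a_j(x) of the source network.
//   record 0: full event recording (times + states).
//   record 1: regular grid, last value at or before each sample time
//             (final value carried forward if the run terminates early).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".ssa_cpp")]]
List ssa_cpp(NumericVector x0, IntegerMatrix stoich, List reactant_idx,
             List reactant_mult, List modifier_idx, NumericVector k,
             double t_max, double seed, int mode, int record,
             int grid_n, double grid_dt, double max_events) {
  const int S = x0.size();
  const int R = k.size();
  std::vector<MAReaction> rx(R);
  for (int j = 0; j < R; ++j) {
    rx[j].k = k[j];
    IntegerVector ri = reactant_idx[j], rm = reactant_mult[j],
                  mi = modifier_idx[j];
    rx[j].ridx.assign(ri.begin(), ri.end());
    rx[j].rmult.assign(rm.begin(), rm.end());
    rx[j].midx.assign(mi.begin(), mi.end());
  }

  // dependency structure
  std::vector<std::vector<int> > touch(R);   // species changed by reaction j
  std::vector<std::vector<int> > dep(S);     // reactions reading species i
  for (int j = 0; j < R; ++j) {
    for (int i = 0; i < S; ++i)
      if (stoich(i, j) != 0) touch[j].push_back(i);
    for (size_t u = 0; u < rx[j].ridx.size(); ++u)
      dep[rx[j].ridx[u]].push_back(j);
    for (size_t u = 0; u < rx[j].midx.size(); ++u)
      dep[rx[j].midx[u]].push_back(j);
  }

  Xoshiro256pp rng((uint64_t)seed);
  std::vector<double> x(x0.begin(), x0.end());

  const int n_chan = (mode == 0) ? R : 2 * S;
  std::vector<double> aj(R);                 // per-reaction propensities
  std::vector<double> drift(S, 0.0);         // qd mode
  std::vector<double> a(n_chan);             // channel propensities
  std::vector<int> stamp_r(R, -1), stamp_s(S, -1);
  std::vector<int> upd_r, upd_s;
  upd_r.reserve(R); upd_s.reserve(S);

  double a0 = 0.0;
  const long long refresh_every = 1 << 16;

  // full propensity refresh
  auto refresh = [&]() {
    a0 = 0.0;
    for (int j = 0; j < R; ++j) aj[j] = ma_propensity(rx[j], x);
    if (mode == 0) {
      for (int j = 0; j < R; ++j) { a[j] = aj[j]; a0 += a[j]; }
    } else {
      for (int i = 0; i < S; ++i) {
        double dsum = 0.0;
        for (int j = 0; j < R; ++j) {
          int s = stoich(i, j);
          if (s != 0) dsum += s * aj[j];
        }
        drift[i] = dsum;
        a[2 * i]     = dsum > 0.0 ?  dsum : 0.0;
        a[2 * i + 1] = dsum < 0.0 ? -dsum : 0.0;
        a0 += a[2 * i] + a[2 * i + 1];
      }
    }
  };
  refresh();

  std::vector<double> rec_t;
  std::vector<double> rec_x;                 // flat, event-major
  NumericMatrix grid;
  int gi = 0;
  if (record == 0) {
    rec_t.reserve(1024);
    rec_x.reserve(1024 * S);
    rec_t.push_back(0.0);
    for (int i = 0; i < S; ++i) rec_x.push_back(x[i]);
  } else {
    grid = NumericMatrix(grid_n, S);
  }

  double t = 0.0;
  long long n_events = 0;
  std::string reason = "t_max";

  auto state_dump = [&](const char *what) {
    std::string dump(what);
    dump += " at t=" + std::to_string(t) + "; state:";
    for (int i = 0; i < S; ++i)
      dump += " " + std::to_string((long long)x[i]);
    stop(dump);
  };

  while (true) {
    if (!std::isfinite(a0)) state_dump("non-finite total propensity");
    if (a0 <= 0.0) {
      // guard against drift-induced false exhaustion
      refresh();
      if (a0 <= 0.0) { reason = "no_reaction"; break; }
    }

    double tau = -std::log(rng.unif()) / a0;
    double t_next = t + tau;
    if (t_next > t_max) break;

    // fill grid samples strictly before the event time
    if (record == 1) {
      while (gi < grid_n && gi * grid_dt < t_next) {
        for (int i = 0; i < S; ++i) grid(gi, i) = x[i];
        ++gi;
      }
    }

    // channel selection: cumulative sum, strict inequality
    double target = rng.unif() * a0;
    double cum = 0.0;
    int chosen = -1;
    for (int j = 0; j < n_chan; ++j) {
      cum += a[j];
      if (cum > target) { chosen = j; break; }
    }
    if (chosen < 0) {  // numerical drift: take the last live channel
      for (int j = n_chan - 1; j >= 0; --j)
        if (a[j] > 0.0) { chosen = j; break; }
      if (chosen < 0) { refresh(); continue; }
    }

    // apply state change; collect affected reactions (deduplicated)
    upd_r.clear();
    if (mode == 0) {
      for (size_t u = 0; u < touch[chosen].size(); ++u) {
        int i = touch[chosen][u];
        x[i] += stoich(i, chosen);
        if (x[i] < 0) state_dump("negative count");
        const std::vector<int> &dd = dep[i];
        for (size_t v = 0; v < dd.size(); ++v)
          if (stamp_r[dd[v]] != (int)(n_events & 0x7FFFFFFF)) {
            stamp_r[dd[v]] = (int)(n_events & 0x7FFFFFFF);
            upd_r.push_back(dd[v]);
          }
      }
      for (size_t v = 0; v < upd_r.size(); ++v) {
        int j = upd_r[v];
        double anew = ma_propensity(rx[j], x);
        a0 += anew - a[j];
        a[j] = anew;
        aj[j] = anew;
      }
    } else {
      int sp = chosen / 2;
      x[sp] += (chosen % 2 == 0) ? 1.0 : -1.0;
      if (x[sp] < 0) state_dump("negative count");
      const std::vector<int> &dd = dep[sp];
      upd_s.clear();
      for (size_t v = 0; v < dd.size(); ++v) {
        int j = dd[v];
        if (stamp_r[j] == (int)(n_events & 0x7FFFFFFF)) continue;
        stamp_r[j] = (int)(n_events & 0x7FFFFFFF);
        double anew = ma_propensity(rx[j], x);
        double delta = anew - aj[j];
        if (delta != 0.0) {
          aj[j] = anew;
          for (size_t u = 0; u < touch[j].size(); ++u) {
            int i = touch[j][u];
            drift[i] += stoich(i, j) * delta;
            if (stamp_s[i] != (int)(n_events & 0x7FFFFFFF)) {
              stamp_s[i] = (int)(n_events & 0x7FFFFFFF);
              upd_s.push_back(i);
            }
          }
        }
      }
      for (size_t v = 0; v < upd_s.size(); ++v) {
        int i = upd_s[v];
        double pos = drift[i] > 0.0 ?  drift[i] : 0.0;
        double neg = drift[i] < 0.0 ? -drift[i] : 0.0;
        a0 += (pos - a[2 * i]) + (neg - a[2 * i + 1]);
        a[2 * i] = pos;
        a[2 * i + 1] = neg;
      }
    }

    t = t_next;
    ++n_events;
    if ((n_events % refresh_every) == 0) {
      refresh();
      Rcpp::checkUserInterrupt();
    }

    if (record == 0) {
      rec_t.push_back(t);
      for (int i = 0; i < S; ++i) rec_x.push_back(x[i]);
    }
    if ((double)n_events >= max_events) state_dump("event budget exceeded");
  }

  if (record == 1) {
    // carry the final value forward to the end of the grid
    while (gi < grid_n) {
      for (int i = 0; i < S; ++i) grid(gi, i) = x[i];
      ++gi;
    }
    return List::create(_["grid"] = grid, _["n_events"] = (double)n_events,
                        _["reason"] = reason);
  }

  int E = rec_t.size();
  NumericVector times(rec_t.begin(), rec_t.end());
  NumericMatrix states(E, S);
  for (int e = 0; e < E; ++e)
    for (int i = 0; i < S; ++i) states(e, i) = rec_x[(size_t)e * S + i];
  return List::create(_["times"] = times, _["states"] = states,
                      _["n_events"] = (double)n_events, _["reason"] = reason);
}
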