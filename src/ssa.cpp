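#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Small counter-seeded RNG (splitmix64 seeding + xoshiro256++), so each
// replicate / cell runs on its own substream derived from the master seed:
// results do not depend on execution order.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0, 1)
    double u;
    do { u = (next() >> 11) * 0x1.0p-53; } while (u <= 0.0);
    return u;
  }
  double rexp(double rate) { return -std::log(unif()) / rate; }
};

struct ChainTables {
  int n, start, absorbing;
  std::vector<double> exit_rate;                  // total rate out of state
  std::vector<std::vector<int> > targets;         // jump targets per state
  std::vector<std::vector<double> > cumrate;      // cumulative jump rates
  ChainTables(const NumericMatrix& Q, int start_, int absorbing_)
      : n(Q.nrow()), start(start_), absorbing(absorbing_),
        exit_rate(n, 0.0), targets(n), cumrate(n) {
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double r = Q(i, j);
        if (r > 0.0) {
          tot += r;
          targets[i].push_back(j);
          cumrate[i].push_back(tot);
        }
      }
      exit_rate[i] = tot;
    }
  }
  // one first-passage trajectory; returns absorption time, optionally
  // appending synthesis-free path tracing is left to the R layer
  double fpt(Xoshiro& rng, int from) const {
    int state = from;
    double t = 0.0;
    while (state != absorbing) {
      double tot = exit_rate[state];
      t += rng.rexp(tot);
      double u = rng.unif() * tot;
      const std::vector<double>& cr = cumrate[state];
      size_t k = 0;
      while (k + 1 < cr.size() && u > cr[k]) ++k;
      state = targets[state][k];
    }
    return t;
  }
};

}  // namespace

// [[Rcpp::export(name = ".ssa_fpt")]]
NumericVector ssa_fpt(NumericMatrix Q, int start, int absorbing, int n_reps,
                      double seed) {
  ChainTables chain(Q, start - 1, absorbing - 1);
  NumericVector out(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    Xoshiro rng(static_cast<uint64_t>(seed) * 0x100000001ULL +
                static_cast<uint64_t>(r));
    out[r] = chain.fpt(rng, chain.start);
  }
  return out;
}

// Population transcript-count simulation. Each cell: first passage from the
// chain_start start state, then repeated cycles; after each synthesis the
// scaffold survives with probability ps (restart on the scaffold chain,
// whose start state may itself be a two-point mixture) and otherwise the
// cell restarts on the full chain. Events strictly before t_end count.
// [[Rcpp::export(name = ".ssa_population")]]
List ssa_population(NumericMatrix Q_full, int start_full, int absorbing_full,
                    NumericMatrix Q_scaf, int absorbing_scaf,
                    IntegerVector scaf_starts, NumericVector scaf_probs,
                    double ps, double t_end, int n_cells, double seed) {
  ChainTables full(Q_full, start_full - 1, absorbing_full - 1);
  ChainTables scaf(Q_scaf, scaf_starts[0] - 1, absorbing_scaf - 1);
  List event_times(n_cells);
  std::vector<int> bursts;  // completed bursts (scaffold broke before t_end)
  for (int c = 0; c < n_cells; ++c) {
    Xoshiro rng(static_cast<uint64_t>(seed) * 0x51F15EED5ULL +
                0x9E3779B9ULL * static_cast<uint64_t>(c + 1));
    std::vector<double> ev;
    double t = full.fpt(rng, full.start);
    int burst = 0;
    while (t < t_end) {
      ev.push_back(t);
      ++burst;
      if (rng.unif() < ps) {
        // scaffold survives: restart at the scaffold state(s)
        int s0 = scaf_starts[0] - 1;
        if (scaf_starts.size() > 1 && rng.unif() >= scaf_probs[0])
          s0 = scaf_starts[1] - 1;
        t += scaf.fpt(rng, s0);
      } else {
        if (t < t_end) bursts.push_back(burst);
        burst = 0;
        t += full.fpt(rng, full.start);
      }
    }
    event_times[c] = wrap(ev);
  }
  return List::create(_["event_times"] = event_times,
                      _["bursts"] = wrap(bursts));
}
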