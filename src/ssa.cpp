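// Exact stochastic simulation (Gillespie direct method) of the negative
// autoregulatory feedback loop with geometric translational bursts:
//   G -> G + mP   rate rho_u, m ~ psi(m) = b^m / (1+b)^(m+1)
//   G + P -> G*   propensity sigma_b * n (gene ON)
//   G* -> G       rate sigma_u
//   P -> 0        propensity d * n
// One trajectory per cell, protein count recorded at the grid times.
// Per-cell RNG streams are derived from the master seed with a splitmix64
// counter scheme so results are invariant to cell ordering and N.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1): 53-bit mantissa, never exactly 0
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

Xoshiro256pp cell_rng(uint64_t master_seed, uint64_t cell_index) {
  uint64_t state = master_seed ^ (0xD1B54A32D192ED03ULL * (cell_index + 1));
  Xoshiro256pp r;
  for (int i = 0; i < 4; ++i) r.s[i] = splitmix64(state);
  return r;
}

// geometric burst size on {0, 1, ...} with mean b: psi(m) = b^m/(1+b)^(m+1)
inline int draw_burst(Xoshiro256pp &rng, double log_q) {
  // m = floor(log(U) / log(b/(1+b)))
  double u = rng.unif();
  return (int)std::floor(std::log(u) / log_q);
}

} // namespace

// [[Rcpp::export(name = ".ssa_population_cpp")]]
IntegerMatrix ssa_population_cpp(NumericVector rho_u, double b, double d,
                                 double sigma_b, double sigma_u,
                                 NumericVector times, double seed) {
  const int n_cells = rho_u.size();
  const int L = times.size();
  IntegerMatrix counts(n_cells, L);
  const double log_q = std::log(b / (1.0 + b));
  const uint64_t ms = (uint64_t)seed;

  for (int cell = 0; cell < n_cells; ++cell) {
    Xoshiro256pp rng = cell_rng(ms, (uint64_t)cell);
    const double rho = rho_u[cell];
    double t = 0.0;
    long n = 0;
    int gene_on = 1;
    int l = 0;
    while (l < L) {
      double a1 = gene_on ? rho : 0.0;             // burst production
      double a2 = gene_on ? sigma_b * n : 0.0;     // binding
      double a3 = gene_on ? 0.0 : sigma_u;         // unbinding
      double a4 = d * n;                            // decay
      double a0 = a1 + a2 + a3 + a4;
      if (a0 <= 0.0) {  // absorbing: record current count at remaining times
        for (; l < L; ++l) counts(cell, l) = (int)n;
        break;
      }
      double tau = -std::log(rng.unif()) / a0;
      while (l < L && t + tau >= times[l]) {
        counts(cell, l) = (int)n;
        ++l;
      }
      if (l >= L) break;
      t += tau;
      double r = rng.unif() * a0;
      if (r < a1) {
        n += draw_burst(rng, log_q);
      } else if (r < a1 + a2) {
        n -= 1; gene_on = 0;
      } else if (r < a1 + a2 + a3) {
        gene_on = 1;
      } else {
        n -= 1;
      }
    }
  }
  return counts;
}

// Single trajectory with burst-size bookkeeping (used to audit the burst law).
// [[Rcpp::export(name = ".ssa_cell_bursts_cpp")]]
List ssa_cell_bursts_cpp(double rho_u, double b, double d, double sigma_b,
                         double sigma_u, NumericVector times, double seed,
                         int cell_index) {
  IntegerMatrix counts = ssa_population_cpp(
      NumericVector::create(rho_u), b, d, sigma_b, sigma_u, times, seed);
  // replay the same stream, recording burst sizes
  Xoshiro256pp rng = cell_rng((uint64_t)seed, (uint64_t)cell_index);
  const double log_q = std::log(b / (1.0 + b));
  const double t_max = times[times.size() - 1];
  std::vector<int> bursts;
  double t = 0.0; long n = 0; int gene_on = 1;
  while (true) {
    double a1 = gene_on ? rho_u : 0.0;
    double a2 = gene_on ? sigma_b * n : 0.0;
    double a3 = gene_on ? 0.0 : sigma_u;
    double a4 = d * n;
    double a0 = a1 + a2 + a3 + a4;
    if (a0 <= 0.0) break;
    t += -std::log(rng.unif()) / a0;
    if (t >= t_max) break;
    double r = rng.unif() * a0;
    if (r < a1) {
      int m = draw_burst(rng, log_q);
      bursts.push_back(m);
      n += m;
    } else if (r < a1 + a2) {
      n -= 1; gene_on = 0;
    } else if (r < a1 + a2 + a3) {
      gene_on = 1;
    } else {
      n -= 1;
    }
  }
  return List::create(_["counts"] = counts, _["bursts"] = wrap(bursts));
}
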