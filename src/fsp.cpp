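// Finite state projection of the feedback-loop master equation.
// State space: {ON, OFF} x {0..n_max}; the probability vector is propagated
// with uniformization, which is exact for the truncated linear system up to
// the Poisson-series tolerance. Probability jumping beyond n_max is absorbed
// (leak) and monitored by the caller.
//
// Layout: index n in 0..n_max for the ON block, n_max+1+n for the OFF block.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct LoopGenerator {
  int nmax, ns;
  double rho, b, d, sb, su;
  std::vector<double> psi;   // psi(1..mcut)
  double burst_out;          // rho * (1 - psi(0)), total burst outflow rate
  double lambda;             // uniformization rate >= max total outflow

  LoopGenerator(int nmax_, double rho_, double b_, double d_, double sb_, double su_)
      : nmax(nmax_), ns(nmax_ + 1), rho(rho_), b(b_), d(d_), sb(sb_), su(su_) {
    double q = b / (1.0 + b);
    int mcut = (b > 0) ? (int)std::ceil(std::log(1e-14) / std::log(q)) : 0;
    if (mcut > nmax) mcut = nmax;
    psi.resize(mcut + 1);
    double p0 = 1.0 / (1.0 + b);
    double w = p0;
    psi[0] = w;
    for (int m = 1; m <= mcut; ++m) { w *= q; psi[m] = w; }
    burst_out = rho * (1.0 - p0);
    double max_on = burst_out + (sb + d) * nmax;
    double max_off = su + d * nmax;
    lambda = std::max(max_on, max_off) + 1e-12;
  }

  // y = x + A x / lambda  (uniformized transition operator)
  void apply(const std::vector<double> &x, std::vector<double> &y) const {
    const double inv = 1.0 / lambda;
    for (int i = 0; i < 2 * ns; ++i) y[i] = x[i];
    for (int n = 0; n <= nmax; ++n) {
      const double pon = x[n], poff = x[ns + n];
      // diagonal outflow
      y[n] -= (burst_out + (sb + d) * n) * pon * inv;
      y[ns + n] -= (su + d * n) * poff * inv;
      // decay
      if (n > 0) {
        y[n - 1] += d * n * pon * inv;
        y[ns + n - 1] += d * n * poff * inv;
      }
      // binding: (ON, n) -> (OFF, n-1)
      if (n > 0) y[ns + n - 1] += sb * n * pon * inv;
      // unbinding: (OFF, n) -> (ON, n)
      y[n] += su * poff * inv;
      // bursts from ON states (m >= 1; jumps beyond nmax leak out)
      if (pon != 0.0) {
        const int mtop = std::min((int)psi.size() - 1, nmax - n);
        const double base = rho * pon * inv;
        for (int m = 1; m <= mtop; ++m) y[n + m] += base * psi[m];
      }
    }
  }
};

} // namespace

// Propagate the initial condition (all mass at ON, n = 0) to each grid time.
// Returns a matrix with one column per grid time (length 2*(nmax+1) rows).
// [[Rcpp::export(name = ".fsp_propagate_cpp")]]
NumericMatrix fsp_propagate_cpp(int nmax, double rho_u, double b, double d,
                                double sigma_b, double sigma_u,
                                NumericVector times, double series_tol) {
  LoopGenerator gen(nmax, rho_u, b, d, sigma_b, sigma_u);
  const int dim = 2 * gen.ns;
  const int L = times.size();
  NumericMatrix out(dim, L);

  std::vector<double> p(dim, 0.0), term(dim), nxt(dim), acc(dim);
  p[0] = 1.0;  // zero proteins, gene ON

  double t_prev = 0.0;
  for (int l = 0; l < L; ++l) {
    double dt = times[l] - t_prev;
    t_prev = times[l];
    if (dt > 0) {
      // substep so exp(-lambda*h) stays representable
      int nsub = std::max(1, (int)std::ceil(gen.lambda * dt / 300.0));
      double h = dt / nsub;
      double lh = gen.lambda * h;
      for (int s = 0; s < nsub; ++s) {
        double w = std::exp(-lh);
        double wsum = w;
        term = p;
        for (int i = 0; i < dim; ++i) acc[i] = w * term[i];
        for (int k = 1; k < 100000; ++k) {
          gen.apply(term, nxt);
          term.swap(nxt);
          w *= lh / k;
          wsum += w;
          for (int i = 0; i < dim; ++i) acc[i] += w * term[i];
          if (k > lh && (1.0 - wsum) < series_tol) break;
        }
        p = acc;
      }
    }
    for (int i = 0; i < dim; ++i) out(i, l) = p[i];
  }
  return out;
}
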