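#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Built-in potential gradients used by the fast integrator path.
// id 1: double well, U = h (z^2 - 1)^2                 params = {h}
// id 2: harmonic,   U = 0.5 kappa z^2                  params = {kappa}
// id 3: separable 2-D, double well (dim 1) + harmonic (dim 2), params = {h, kappa}
// id 4: Mueller-like 2-D, sum of ng Gaussian wells:
//       U = sum_i A_i exp(-((x-ax_i)^2 + (y-ay_i)^2) / (2 s_i^2))
//       params = {ng, A..., ax..., ay..., s...}
static inline void grad_pot(int id, const double *p, const double *z, int d,
                            double *g) {
  switch (id) {
  case 1:
    g[0] = 4.0 * p[0] * z[0] * (z[0] * z[0] - 1.0);
    break;
  case 2:
    g[0] = p[0] * z[0];
    break;
  case 3:
    g[0] = 4.0 * p[0] * z[0] * (z[0] * z[0] - 1.0);
    g[1] = p[1] * z[1];
    break;
  case 4: {
    int ng = (int)p[0];
    const double *A = p + 1, *ax = p + 1 + ng, *ay = p + 1 + 2 * ng,
                 *s = p + 1 + 3 * ng;
    g[0] = 0.0;
    g[1] = 0.0;
    for (int i = 0; i < ng; ++i) {
      double dx = z[0] - ax[i], dy = z[1] - ay[i];
      double s2 = s[i] * s[i];
      double e = A[i] * std::exp(-(dx * dx + dy * dy) / (2.0 * s2));
      g[0] += -e * dx / s2;
      g[1] += -e * dy / s2;
    }
    break;
  }
  default:
    Rcpp::stop("unknown potential id");
  }
}

// Overdamped Langevin (Euler-Maruyama):
//   z[t+1] = z[t] - D grad U(z[t]) dt + sqrt(2 D dt / beta) xi,  xi ~ N(0,1)
// Returns every `thin`-th state (including the state after the first step).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".sim_langevin_cpp")]]
NumericMatrix sim_langevin_cpp(int pot_id, NumericVector params,
                               NumericVector z0, double beta, double dt,
                               double n_steps_d, int thin, double D,
                               double bound) {
  long long n_steps = (long long)n_steps_d;
  int d = z0.size();
  long long n_out = n_steps / thin;
  NumericMatrix out((int)n_out, d);
  std::vector<double> z(z0.begin(), z0.end()), g(d);
  double drift = D * dt;
  double noise = R_finite(beta) ? std::sqrt(2.0 * D * dt / beta) : 0.0;
  const double *p = params.begin();
  RNGScope scope;
  long long row = 0;
  for (long long t = 1; t <= n_steps; ++t) {
    grad_pot(pot_id, p, z.data(), d, g.data());
    for (int j = 0; j < d; ++j) {
      z[j] += -drift * g[j] + (noise > 0.0 ? noise * norm_rand() : 0.0);
      if (std::fabs(z[j]) > bound || !R_finite(z[j]))
        Rcpp::stop("trajectory diverged (|z| > %g at step %lld); "
                   "reduce the time step dt", bound, t);
    }
    if (t % thin == 0) {
      for (int j = 0; j < d; ++j)
        out((int)row, j) = z[j];
      ++row;
    }
  }
  return out;
}
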