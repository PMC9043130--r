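#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integrator for overdamped Langevin dynamics on a 1-D
// coordinate with position-dependent diffusion:
//   z <- z + [beta*D(z)*F(z) + D'(z)]*dt + sqrt(2*D(z)*dt)*xi
// The D'(z) spurious-drift term (Ito convention) keeps the stationary law
// Boltzmann when D varies with position. Force F = -d(w + biases)/dz, D and
// D' are supplied as values on a uniform grid and linearly interpolated;
// the caller folds biases and constant (field) forces into the force grid.
// Random numbers come from the R RNG so set.seed() governs reproducibility.

struct Grid {
  const double *v;
  double z0, dz;
  int n;
  double at(double z) const {
    double x = (z - z0) / dz;
    if (x <= 0) return v[0];
    if (x >= n - 1) return v[n - 1];
    int i = (int)x;
    double f = x - i;
    return v[i] * (1 - f) + v[i + 1] * f;
  }
};

static inline double reflect_into(double z, double lo, double hi) {
  // mirror reflection; loop in case of a (rare) large excursion
  for (int it = 0; it < 64 && (z < lo || z > hi); ++it) {
    if (z < lo) z = 2 * lo - z;
    if (z > hi) z = 2 * hi - z;
  }
  if (z < lo) z = lo;
  if (z > hi) z = hi;
  return z;
}

// boundary_mode: 0 = error on escape, 1 = reflect at [b_lo, b_hi],
//                2 = periodic wrap on [b_lo, b_hi] (wrap count recorded)
// [[Rcpp::export]]
List bd_run_core(double z0, double n_steps_d, double dt, int out_stride,
                 NumericVector grid_z0dz, // c(z0, dz, n)
                 NumericVector Fg, NumericVector Dg, NumericVector dDg,
                 double beta, double b_lo, double b_hi, int boundary_mode) {
  long long n_steps = (long long)n_steps_d;
  Grid F{REAL(Fg), grid_z0dz[0], grid_z0dz[1], (int)grid_z0dz[2]};
  Grid D{REAL(Dg), grid_z0dz[0], grid_z0dz[1], (int)grid_z0dz[2]};
  Grid dD{REAL(dDg), grid_z0dz[0], grid_z0dz[1], (int)grid_z0dz[2]};
  long long n_out = n_steps / out_stride + 1;
  NumericVector out(n_out);
  IntegerVector wraps(boundary_mode == 2 ? n_out : 1);
  double z = z0;
  int wrap = 0;
  double L = b_hi - b_lo;
  out[0] = z;
  if (boundary_mode == 2) wraps[0] = 0;
  RNGScope scope;
  long long k = 1;
  for (long long s = 1; s <= n_steps; ++s) {
    double Dz = D.at(z);
    double drift = beta * Dz * F.at(z) + dD.at(z);
    z += drift * dt + std::sqrt(2.0 * Dz * dt) * norm_rand();
    if (boundary_mode == 1) {
      z = reflect_into(z, b_lo, b_hi);
    } else if (boundary_mode == 2) {
      while (z >= b_hi) { z -= L; ++wrap; }
      while (z < b_lo)  { z += L; --wrap; }
    } else {
      if (z < b_lo || z > b_hi)
        stop("domain escape at step %lld: z = %g outside [%g, %g]",
             s, z, b_lo, b_hi);
    }
    if (s % out_stride == 0) {
      out[k] = z;
      if (boundary_mode == 2) wraps[k] = wrap;
      ++k;
    }
  }
  return List::create(_["z"] = out, _["wraps"] = wraps);
}

// First-passage run: step until z <= a_lo (side -1) or z >= a_hi (side +1).
// A non-finite absorbing bound disables that side; reflection applies at
// [b_lo, b_hi]. Returns time, exit side and a censored flag when the step
// budget is exhausted.
// [[Rcpp::export]]
List bd_fpt_core(NumericVector z0s, double dt,
                 NumericVector grid_z0dz,
                 NumericVector Fg, NumericVector Dg, NumericVector dDg,
                 double beta, double b_lo, double b_hi,
                 double a_lo, double a_hi, double max_steps_d) {
  int n_rep = z0s.size();
  long long max_steps = (long long)max_steps_d;
  Grid F{REAL(Fg), grid_z0dz[0], grid_z0dz[1], (int)grid_z0dz[2]};
  Grid D{REAL(Dg), grid_z0dz[0], grid_z0dz[1], (int)grid_z0dz[2]};
  Grid dD{REAL(dDg), grid_z0dz[0], grid_z0dz[1], (int)grid_z0dz[2]};
  bool has_lo = R_finite(a_lo), has_hi = R_finite(a_hi);
  NumericVector times(n_rep);
  IntegerVector side(n_rep);
  LogicalVector censored(n_rep);
  RNGScope scope;
  for (int r = 0; r < n_rep; ++r) {
    double z = z0s[r];
    long long s = 0;
    int sd = 0;
    bool cens = true;
    for (s = 1; s <= max_steps; ++s) {
      double Dz = D.at(z);
      z += (beta * Dz * F.at(z) + dD.at(z)) * dt +
           std::sqrt(2.0 * Dz * dt) * norm_rand();
      if (has_lo && z <= a_lo) { sd = -1; cens = false; break; }
      if (has_hi && z >= a_hi) { sd = +1; cens = false; break; }
      z = reflect_into(z, b_lo, b_hi);
    }
    times[r] = (double)s * dt;
    side[r] = sd;
    censored[r] = cens;
  }
  return List::create(_["time"] = times, _["side"] = side,
                      _["censored"] = censored);
}
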