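#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bernoulli function B(x) = x / (exp(x) - 1), stable near 0.
static inline double bern(double x) {
  if (std::fabs(x) < 1e-10) return 1.0 - 0.5 * x + x * x / 12.0;
  if (x > 500.0) return 0.0;           // exp overflow guard
  if (x < -500.0) return -x;           // B(-|x|) -> |x|
  return x / (std::expm1(x));
}

// Conservative finite-volume Lamm-equation solver on a uniform radial grid
// with Scharfetter-Gummel (exponential-fitting) face fluxes and
// Crank-Nicolson time stepping.
//
// PDE: dc/dt = -(1/r) d/dr [ r (s w^2 r c - D dc/dr) ], no-flux at both ends.
//
// c0       : initial cell-average concentrations (n cells)
// r_m      : meniscus radius (m); cell width h = (r_b - r_m)/n
// h        : cell width (m)
// D        : diffusion coefficient (m^2/s)
// somega2  : s * omega^2 (1/s)
// times    : strictly increasing output times (s), starting >= 0
// dt_max   : maximum time step (s)
//
// Returns a length(times) x n matrix of concentration profiles.
// [[Rcpp::export]]
NumericMatrix lamm_march(NumericVector c0, double r_m, double h,
                         double D, double somega2,
                         NumericVector times, double dt_max) {
  const int n = c0.size();
  const int nt = times.size();
  NumericMatrix out(nt, n);
  std::vector<double> c(c0.begin(), c0.end());

  // Tridiagonal generator L (dc/dt = L c): sub, diag, super.
  std::vector<double> Lsub(n, 0.0), Ldia(n, 0.0), Lsup(n, 0.0);
  for (int j = 0; j < n - 1; ++j) {
    // face between cells j and j+1 at radius r_f
    const double r_f = r_m + (j + 1) * h;
    const double r_lo = r_m + (j + 0.5) * h;
    const double r_hi = r_m + (j + 1.5) * h;
    const double v = somega2 * r_f; // outward advection velocity at face
    double a_lo, a_hi;              // J = a_lo * c_j - a_hi * c_{j+1}
    if (D > 0.0) {
      const double p = v * h / D;
      a_lo = (D / h) * bern(-p);
      a_hi = (D / h) * bern(p);
    } else { // pure advection: upwind
      if (v >= 0.0) { a_lo = v; a_hi = 0.0; }
      else          { a_lo = 0.0; a_hi = -v; }
    }
    const double flo = r_f / (r_lo * h);
    const double fhi = r_f / (r_hi * h);
    Ldia[j]     -= flo * a_lo;
    Lsup[j]     += flo * a_hi;
    Lsub[j + 1] += fhi * a_lo;
    Ldia[j + 1] -= fhi * a_hi;
  }

  // Thomas algorithm workspace
  std::vector<double> aa(n), bb(n), cc(n), dd(n), cp(n), dp(n), rhs(n);

  double t_cur = 0.0;
  for (int k = 0; k < nt; ++k) {
    const double t_target = times[k];
    if (t_target > t_cur) {
      const double span = t_target - t_cur;
      const int nsteps = (int)std::ceil(span / dt_max);
      const double dt = span / nsteps;
      // CN matrices: M1 = I - dt/2 L (solve), M2 = I + dt/2 L (multiply)
      for (int i = 0; i < n; ++i) {
        aa[i] = -0.5 * dt * Lsub[i];
        bb[i] = 1.0 - 0.5 * dt * Ldia[i];
        cc[i] = -0.5 * dt * Lsup[i];
      }
      for (int step = 0; step < nsteps; ++step) {
        // rhs = M2 c
        for (int i = 0; i < n; ++i) {
          double v = (1.0 + 0.5 * dt * Ldia[i]) * c[i];
          if (i > 0)     v += 0.5 * dt * Lsub[i] * c[i - 1];
          if (i < n - 1) v += 0.5 * dt * Lsup[i] * c[i + 1];
          rhs[i] = v;
        }
        // Thomas solve M1 x = rhs
        cp[0] = cc[0] / bb[0];
        dp[0] = rhs[0] / bb[0];
        for (int i = 1; i < n; ++i) {
          const double m = bb[i] - aa[i] * cp[i - 1];
          cp[i] = cc[i] / m;
          dp[i] = (rhs[i] - aa[i] * dp[i - 1]) / m;
        }
        c[n - 1] = dp[n - 1];
        for (int i = n - 2; i >= 0; --i) c[i] = dp[i] - cp[i] * c[i + 1];
      }
      t_cur = t_target;
    }
    for (int i = 0; i < n; ++i) out(k, i) = c[i];
  }
  return out;
}
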