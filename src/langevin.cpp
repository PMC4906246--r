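#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of a tabulated force on a uniform grid.
// Positions outside the grid take the edge value (the caller installs
// reflecting walls at the grid edges, so this only matters transiently).
static inline double interp_force(const double z, const double z0,
                                  const double inv_dz, const int n,
                                  const double *f) {
  double u = (z - z0) * inv_dz;
  if (u <= 0.0) return f[0];
  if (u >= n - 1) return f[n - 1];
  int i = (int)u;
  double w = u - i;
  return f[i] * (1.0 - w) + f[i + 1] * w;
}

static inline double reflect(double z, const double lo, const double hi) {
  // fold back into [lo, hi]; loop handles overshoot past both walls
  for (int k = 0; k < 64 && (z < lo || z > hi); ++k) {
    if (z < lo) z = 2.0 * lo - z;
    if (z > hi) z = 2.0 * hi - z;
  }
  return z;
}

// Overdamped (Brownian) dynamics on a 1D tabulated potential:
//   z <- z + D*dt*F_eff(z)/kT + sqrt(2*D*dt)*eta
// F_eff = tabulated force (already includes any voltage tilt) plus an
// optional harmonic bias -kappa*(z - center). Reflecting boundaries at
// [lo, hi]. Uses R's RNG, so results are reproducible under set.seed().
// Samples are recorded every `stride` steps after `burnin` steps.
//
// With metropolis = true the Euler move becomes a MALA proposal that
// is accepted with the usual Metropolis-Hastings ratio, making the
// stationary distribution exactly Boltzmann at any stable dt (the
// plain Euler chain carries an O(dt) density error whose tails bias
// stiff umbrella windows).
// [[Rcpp::export]]
NumericVector cpp_langevin(const NumericVector grid_z,
                           const NumericVector grid_force,
                           const NumericVector grid_pot,
                           const double z_init, const double D,
                           const double dt, const double kT,
                           const int n_steps, const int burnin,
                           const int stride, const double kappa,
                           const double center, const double lo,
                           const double hi, const bool metropolis) {
  const int ng = grid_z.size();
  if (ng < 2) stop("force grid needs >= 2 points");
  const double g0 = grid_z[0];
  const double inv_dz = (ng - 1) / (grid_z[ng - 1] - g0);
  const double mob = D * dt / kT;
  const double noise = std::sqrt(2.0 * D * dt);
  const double *f = &grid_force[0];
  const double *U = &grid_pot[0];

  int n_out = n_steps / stride;
  NumericVector out(n_out);
  RNGScope scope;
  double z = z_init;
  int total = burnin + n_steps;
  int j = 0;
  for (int i = 0; i < total; ++i) {
    double F = interp_force(z, g0, inv_dz, ng, f);
    if (kappa > 0.0) F -= kappa * (z - center);
    double znew = z + mob * F + noise * R::norm_rand();
    if (!std::isfinite(znew) || std::fabs(znew) > 1e6)
      stop("Langevin step diverged (dt = %g too large for this stiffness)", dt);
    if (metropolis) {
      double Fn = interp_force(znew, g0, inv_dz, ng, f);
      if (kappa > 0.0) Fn -= kappa * (znew - center);
      double Uz = interp_force(z, g0, inv_dz, ng, U) +
                  (kappa > 0.0 ? 0.5 * kappa * (z - center) * (z - center) : 0.0);
      double Un = interp_force(znew, g0, inv_dz, ng, U) +
                  (kappa > 0.0 ? 0.5 * kappa * (znew - center) * (znew - center) : 0.0);
      double fwd = znew - z - mob * F;    // forward noise
      double bwd = z - znew - mob * Fn;   // reverse noise
      double logA = -(Un - Uz) / kT -
                    (bwd * bwd - fwd * fwd) / (2.0 * noise * noise);
      if (logA < 0.0 && std::log(unif_rand()) >= logA) znew = z;
    }
    z = reflect(znew, lo, hi);
    if (i >= burnin) {
      int k = i - burnin;
      if ((k + 1) % stride == 0) out[j++] = z;
    }
  }
  return out;
}

// First-passage simulation: run until z >= z_absorb (or max_steps).
// Reflecting wall at z_reflect. Returns the passage time in ps, or NA
// if the horizon is reached first.
// [[Rcpp::export]]
double cpp_first_passage(const NumericVector grid_z,
                         const NumericVector grid_force,
                         const double z_init, const double D,
                         const double dt, const double kT,
                         const double z_reflect, const double z_absorb,
                         const double max_steps) {
  const int ng = grid_z.size();
  if (ng < 2) stop("force grid needs >= 2 points");
  const double g0 = grid_z[0];
  const double inv_dz = (ng - 1) / (grid_z[ng - 1] - g0);
  const double mob = D * dt / kT;
  const double noise = std::sqrt(2.0 * D * dt);
  const double *f = &grid_force[0];

  RNGScope scope;
  double z = z_init;
  const long long n_max = (long long)max_steps;
  for (long long i = 0; i < n_max; ++i) {
    double F = interp_force(z, g0, inv_dz, ng, f);
    z += mob * F + noise * R::norm_rand();
    if (!std::isfinite(z))
      stop("Langevin step diverged (dt = %g too large)", dt);
    if (z < z_reflect) z = 2.0 * z_reflect - z;
    if (z >= z_absorb) return (i + 1) * dt;
  }
  return NA_REAL;
}
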