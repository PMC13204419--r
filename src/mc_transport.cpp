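#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Photon-packet random walk in a homogeneous semi-infinite medium
// (MCML-style): exponential step lengths at mu_t, Henyey-Greenstein
// scattering, implicit-capture weight decay by mu_a/mu_t, Russian roulette
// below w_roulette, matched boundary (all photons crossing z < 0 escape and
// score into r-binned reflectance). Absorbed weight scores the (r, z)
// deposition grid; fluence = deposited / (mu_a * cell volume * n_photons).
//
// Tallies are kept so that the accounting identity
//   launched = escaped + absorbed + (roulette_killed - roulette_gain)
//              + truncated
// holds to floating-point precision for every seed. Roulette survivors gain
// weight (w/p - w), which is recorded in roulette_gain.
//
// Uses R's RNG (unif_rand) so reproducibility is controlled by set.seed()
// in the calling R wrapper.

// [[Rcpp::export]]
List mc_transport_cpp(double mu_a, double mu_s_prime, double g,
                      int n_photons, double r_max, double z_max, double bin,
                      double w_roulette, double roulette_p, double max_steps) {
  if (mu_s_prime <= 0.0) stop("mu_s_prime must be > 0");
  double mu_s = (g < 1.0) ? mu_s_prime / (1.0 - g) : mu_s_prime;
  double mu_t = mu_a + mu_s;
  int nr = (int)std::ceil(r_max / bin);
  int nz = (int)std::ceil(z_max / bin);
  NumericVector refl(nr);        // escaped weight per radial bin
  NumericMatrix adep(nr, nz);    // absorbed weight per (r, z) cell
  double escaped = 0.0, absorbed = 0.0;
  double roulette_killed = 0.0, roulette_gain = 0.0, truncated = 0.0;
  double escaped_beyond = 0.0;   // escaped at r >= r_max (not binned)

  RNGScope scope;
  for (int i = 0; i < n_photons; ++i) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;  // launched downward at the origin
    double w = 1.0;
    double steps = 0.0;
    for (;;) {
      if (++steps > max_steps) { truncated += w; break; }
      double s = -std::log(unif_rand()) / mu_t;
      double z_new = z + uz * s;
      if (z_new < 0.0) {
        // crosses the surface: propagate to the boundary and escape
        double s_b = -z / uz;  // uz < 0 here
        double xb = x + ux * s_b, yb = y + uy * s_b;
        double r = std::sqrt(xb * xb + yb * yb);
        escaped += w;
        int ir = (int)(r / bin);
        if (ir < nr) refl[ir] += w; else escaped_beyond += w;
        break;
      }
      x += ux * s; y += uy * s; z = z_new;
      if (mu_a > 0.0) {
        double dw = w * mu_a / mu_t;
        absorbed += dw;
        double r = std::sqrt(x * x + y * y);
        int ir = (int)(r / bin), iz = (int)(z / bin);
        if (ir < nr && iz < nz) adep(ir, iz) += dw;
        w -= dw;
      }
      if (w < w_roulette) {
        if (unif_rand() < roulette_p) {
          roulette_gain += w / roulette_p - w;
          w /= roulette_p;
        } else {
          roulette_killed += w;
          break;
        }
      }
      // Henyey-Greenstein deflection
      double ct;
      if (g == 0.0) {
        ct = 2.0 * unif_rand() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      }
      if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = (uz >= 0.0) ? ct : -ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double uxn = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double uyn = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double uzn = -st * cp * den + uz * ct;
        ux = uxn; uy = uyn; uz = uzn;
        double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= norm; uy /= norm; uz /= norm;
      }
    }
  }

  return List::create(
    _["refl_weight"] = refl,
    _["absorbed_weight"] = adep,
    _["escaped"] = escaped,
    _["escaped_beyond_rmax"] = escaped_beyond,
    _["absorbed"] = absorbed,
    _["roulette_killed"] = roulette_killed,
    _["roulette_gain"] = roulette_gain,
    _["truncated"] = truncated);
}
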