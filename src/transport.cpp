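#include <Rcpp.h>
using namespace Rcpp;

// Weighted Monte Carlo photon transport for a focused, underfilled-objective
// beam scanned over a disk FOV in layered turbid tissue.
//
// Conventions: lengths in mm, z = 0 at the tissue surface, z increasing into
// the tissue. Photons are launched on the surface converging towards a focal
// point at depth z_focus (Gaussian back-aperture fill), propagated with
// exponential free paths, Henyey-Greenstein scattering and implicit-capture
// absorption, and terminated by Russian roulette or boundary crossing.
//
// Weight accounting is exact: every unit of launched weight ends up in one of
// {deposited (heating), window, skull, escaped, roulette_net}, where
// roulette_net is the net weight destroyed minus created by the roulette
// (zero in expectation; identically zero when roulette is disabled except for
// the hard-floor residual, which is also booked there).

static inline double hg_cost(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - tmp * tmp) / (2.0 * g);
}

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(int n_photons,
                      double z_focus_mm,
                      double fov_radius_mm,
                      double w0_mm,
                      double focal_length_mm,
                      double n0,
                      NumericVector mua,        // per layer, 1/mm
                      NumericVector mus,        // per layer, 1/mm
                      NumericVector g,          // per layer
                      NumericVector layer_zmax, // per layer upper z bound, mm
                      double escape_r_mm,
                      double escape_z_mm,
                      double window_r_mm,
                      int nr, int nz,
                      double dr_mm, double dz_mm,
                      bool roulette = true) {
  const int nlay = mua.size();
  if (mus.size() != nlay || g.size() != nlay || layer_zmax.size() != nlay)
    stop("layer parameter vectors must have equal length");

  NumericMatrix grid(nr, nz);
  double heating = 0.0, window = 0.0, skull = 0.0, escaped = 0.0;
  double roulette_net = 0.0;
  const double launched = (double)n_photons;
  const double wmin = 1e-4, psurv = 0.1, wfloor = 1e-7;
  const int max_steps = 1000000;

  for (int ip = 0; ip < n_photons; ++ip) {
    if (ip % 65536 == 0) Rcpp::checkUserInterrupt();

    // focal position scanned uniformly over the FOV disk (telecentric)
    double xf = 0.0, yf = 0.0;
    if (fov_radius_mm > 0.0) {
      double rf = fov_radius_mm * std::sqrt(unif_rand());
      double pf = 2.0 * M_PI * unif_rand();
      xf = rf * std::cos(pf);
      yf = rf * std::sin(pf);
    }

    // Gaussian back-aperture fill: radial draw, resample over-aperture tails
    double w, sin_th;
    do {
      double X = unif_rand();
      while (X <= 0.0) X = unif_rand();
      w = w0_mm * std::sqrt(-std::log(X) / 2.0);
      sin_th = w / (n0 * focal_length_mm);
    } while (sin_th > 1.0);
    double theta = std::asin(sin_th);
    double cos_th = std::cos(theta);
    double phi = 2.0 * M_PI * unif_rand();
    double r0 = std::tan(theta) * z_focus_mm;

    // entry point on the surface, direction converging to the focal point
    double x = xf + r0 * std::cos(phi);
    double y = yf + r0 * std::sin(phi);
    double z = 0.0;
    double ux = -sin_th * std::cos(phi);
    double uy = -sin_th * std::sin(phi);
    double uz = cos_th;

    double W = 1.0;
    int lay = 0;

    for (int step = 0; step < max_steps; ++step) {
      // locate layer
      lay = 0;
      while (lay < nlay - 1 && z > layer_zmax[lay]) ++lay;
      double mut = mua[lay] + mus[lay];
      if (mut <= 0.0) { // transparent medium: fly straight out
        escaped += W;
        break;
      }
      double u = unif_rand();
      while (u <= 0.0) u = unif_rand();
      double s = -std::log(u) / mut;

      double nx = x + s * ux, ny = y + s * uy, nzp = z + s * uz;

      if (nzp < 0.0) { // exits through the top surface
        double t = -z / (s * uz);
        double ex = x + t * s * ux, ey = y + t * s * uy;
        double rexit = std::sqrt(ex * ex + ey * ey);
        if (rexit <= window_r_mm) window += W; else skull += W;
        W = 0.0;
        break;
      }
      double rr = std::sqrt(nx * nx + ny * ny);
      if (nzp > escape_z_mm || rr > escape_r_mm) {
        escaped += W;
        W = 0.0;
        break;
      }

      x = nx; y = ny; z = nzp;

      // implicit-capture absorption deposit at the new position
      double dw = W * mua[lay] / mut;
      if (dw > 0.0) {
        heating += dw;
        int ir = (int)(rr / dr_mm);
        int iz = (int)(z / dz_mm);
        if (ir >= 0 && ir < nr && iz >= 0 && iz < nz) grid(ir, iz) += dw;
        W -= dw;
      }
      if (!(W > 0.0) || !R_finite(W)) { // fully absorbed or numeric abort
        if (!R_finite(W)) stop("NaN photon weight encountered");
        break;
      }

      // Henyey-Greenstein spin
      double cost = hg_cost(g[lay], unif_rand());
      if (cost > 1.0) cost = 1.0;
      if (cost < -1.0) cost = -1.0;
      double sint = std::sqrt(1.0 - cost * cost);
      double psi = 2.0 * M_PI * unif_rand();
      double cosp = std::cos(psi), sinp = std::sin(psi);
      if (std::fabs(uz) > 0.99999) {
        ux = sint * cosp;
        uy = sint * sinp;
        uz = cost * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double tux = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
        double tuy = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
        double tuz = -sint * cosp * den + uz * cost;
        ux = tux; uy = tuy; uz = tuz;
        double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= norm; uy /= norm; uz /= norm;
      }

      // Russian roulette (with exact weight bookkeeping)
      if (W < wmin) {
        if (roulette) {
          if (unif_rand() < psurv) {
            roulette_net -= W * (1.0 / psurv - 1.0);
            W /= psurv;
          } else {
            roulette_net += W;
            W = 0.0;
            break;
          }
        } else if (W < wfloor) {
          roulette_net += W; // hard-floor residual, O(1e-7) per photon
          W = 0.0;
          break;
        }
      }
    }
  }

  return List::create(
    _["grid"] = grid,
    _["heating"] = heating,
    _["window"] = window,
    _["skull"] = skull,
    _["escaped"] = escaped,
    _["roulette_net"] = roulette_net,
    _["launched"] = launched);
}
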