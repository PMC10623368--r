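// Voxelized Monte Carlo photon transport in axisymmetric labeled media.
//
// Photon packets are launched from the fiber face (uniform over the core,
// directions uniform in solid angle within the NA cone) and stepped in
// fixed increments; within each increment the packet weight is attenuated
// by exp(-mu_a * ds) of the local medium and the complement is deposited in
// the local (r, z) voxel, which makes the energy bookkeeping
// absorbed + transmitted + escaped = launched exact to round-off.
// Scattering (Henyey-Greenstein) is applied when the accumulated scattering
// optical depth reaches an exponentially sampled target. Transport
// terminates at the target plane z = z_target (energy tallied as
// "transmitted", i.e. delivered to the stone surface).

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - f * f) / (2.0 * g);
}

// [[Rcpp::export]]
List mc_trace_cpp(IntegerMatrix labels, double dr, double dz,
                  NumericVector mua, NumericVector mus, NumericVector gpar,
                  double z_target, double core_radius, double sin_theta_max,
                  int n_photons, double energy, double step, int seed,
                  bool collimated) {
  const int nr = labels.nrow(), nz = labels.ncol();
  const double rmax = nr * dr, zmax = nz * dz;
  NumericMatrix absorbed(nr, nz);
  double transmitted = 0.0, escaped = 0.0;
  const double wmin = 1e-6;

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  const double cos_max = std::sqrt(std::max(0.0, 1.0 - sin_theta_max * sin_theta_max));

  for (int ph = 0; ph < n_photons; ++ph) {
    // launch point uniform over the fiber core disk at z = 0
    double rr = core_radius * std::sqrt(U(rng));
    double phi = 2.0 * M_PI * U(rng);
    double x = rr * std::cos(phi), y = rr * std::sin(phi), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    if (!collimated) {
      double ct = cos_max + (1.0 - cos_max) * U(rng); // uniform in solid angle
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double ph2 = 2.0 * M_PI * U(rng);
      ux = st * std::cos(ph2); uy = st * std::sin(ph2); uz = ct;
    }
    double w = 1.0;
    double tau_acc = 0.0, tau_next = -std::log(U(rng));

    for (;;) {
      double r = std::sqrt(x * x + y * y);
      int ir = (int)(r / dr); if (ir >= nr) ir = nr - 1;
      int iz = (int)(z / dz); if (iz >= nz) iz = nz - 1; if (iz < 0) iz = 0;
      int lab = labels(ir, iz) - 1; // labels arrive 1-based from R

      double s = step;
      int exit_kind = 0; // 1 target plane, 2 top face, 3 bottom face
      if (uz > 0.0 && z + s * uz >= z_target) { s = (z_target - z) / uz; exit_kind = 1; }
      else if (uz > 0.0 && z + s * uz >= zmax) { s = (zmax - z) / uz; exit_kind = 3; }
      else if (uz < 0.0 && z + s * uz <= 0.0)  { s = -z / uz; exit_kind = 2; }

      double att = std::exp(-mua[lab] * s);
      absorbed(ir, iz) += w * (1.0 - att);
      w *= att;
      x += ux * s; y += uy * s; z += uz * s;

      if (exit_kind == 1) { transmitted += w; break; }
      if (exit_kind == 2 || exit_kind == 3) { escaped += w; break; }
      if (x * x + y * y >= rmax * rmax) { escaped += w; break; }

      if (mus[lab] > 0.0) {
        tau_acc += mus[lab] * s;
        if (tau_acc >= tau_next) {
          double ct = hg_cos(gpar[lab], U(rng));
          double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
          double ps = 2.0 * M_PI * U(rng);
          double cp = std::cos(ps), sp = std::sin(ps);
          if (std::fabs(uz) > 0.99999) {
            ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
          } else {
            double den = std::sqrt(1.0 - uz * uz);
            double nx = (st * (ux * uz * cp - uy * sp)) / den + ux * ct;
            double ny = (st * (uy * uz * cp + ux * sp)) / den + uy * ct;
            double nzv = -st * cp * den + uz * ct;
            ux = nx; uy = ny; uz = nzv;
            double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= nn; uy /= nn; uz /= nn;
          }
          tau_acc = 0.0;
          tau_next = -std::log(U(rng));
        }
      }
      if (w < wmin) { absorbed(ir, iz) += w; break; } // terminal deposit, exact bookkeeping
    }
  }

  double scale = energy / n_photons;
  double abs_total = 0.0;
  for (int j = 0; j < nz; ++j)
    for (int i = 0; i < nr; ++i) { absorbed(i, j) *= scale; abs_total += absorbed(i, j); }
  return List::create(_["absorbed"] = absorbed,
                      _["absorbed_total"] = abs_total,
                      _["transmitted"] = transmitted * scale,
                      _["escaped"] = escaped * scale,
                      _["launched"] = energy);
}
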