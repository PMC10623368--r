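// Axisymmetric velocity-stress staggered-grid elastodynamics.
//
// One unified update rule covers the fluid (mu = 0, lambda = rho c^2) and
// the elastic solid; the fluid-solid interface needs no explicit coupling
// condition because the harmonic average of mu vanishes there, enforcing
// zero shear traction while normal traction and velocity remain continuous.
//
// Staggering (square cells of side h):
//   sigma_rr, sigma_tt, sigma_zz, material at cell centers (i+1/2, j+1/2)
//   v_r at (i, j+1/2) with v_r = 0 on the axis i = 0
//   v_z at (i+1/2, j)
//   sigma_rz at (i, j)
// z increases downward (from the fluid into the solid).
//
// A monopole source adds an isotropic stress increment at an on-axis cell.
// Sponge layers damp the fields near the outer boundaries.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List wave_sim_cpp(NumericMatrix lambda, NumericMatrix mu, NumericMatrix rho,
                  double h, double dt, int nsteps,
                  IntegerVector src_i, IntegerVector src_j,
                  NumericVector src_w, NumericVector src_series,
                  IntegerVector station_i, IntegerVector station_j,
                  IntegerVector snap_steps, int sponge_cells,
                  double sponge_strength, int energy_every) {
  const int nr = lambda.nrow(), nz = lambda.ncol();

  NumericMatrix srr(nr, nz), stt(nr, nz), szz(nr, nz);
  NumericMatrix vr(nr + 1, nz), vz(nr, nz + 1), srz(nr + 1, nz + 1);

  // sponge damping profiles (1 in the interior, < 1 near outer edges)
  std::vector<double> damp_r(nr + 1, 1.0), damp_z(nz + 1, 1.0);
  for (int i = 0; i <= nr; ++i) {
    int d = nr - i; // distance from outer radial edge in cells
    if (d < sponge_cells) {
      double x = (double)(sponge_cells - d) / sponge_cells;
      damp_r[i] = std::exp(-sponge_strength * x * x);
    }
  }
  for (int j = 0; j <= nz; ++j) {
    int d = std::min(j, nz - j); // both z faces absorbing
    if (d < sponge_cells) {
      double x = (double)(sponge_cells - d) / sponge_cells;
      damp_z[j] = std::exp(-sponge_strength * x * x);
    }
  }

  const int n_st = station_i.size();
  NumericMatrix st_srr(nsteps, n_st), st_stt(nsteps, n_st),
                st_szz(nsteps, n_st), st_srz(nsteps, n_st);
  List snapshots;
  std::vector<int> snap_at(snap_steps.begin(), snap_steps.end());
  std::vector<double> energy;

  for (int n = 0; n < nsteps; ++n) {
    // --- velocity update (uses stresses at time level n) ---
    for (int j = 0; j < nz; ++j) {
      for (int i = 1; i < nr; ++i) { // vr on axis (i = 0) stays 0
        double rhob = 0.5 * (rho(i - 1, j) + rho(i, j));
        double rnode = i * h;
        double dsrr = (srr(i, j) - srr(i - 1, j)) / h;
        double dsrz = (srz(i, j + 1) - srz(i, j)) / h;
        double hoop = 0.5 * (srr(i - 1, j) + srr(i, j) - stt(i - 1, j) - stt(i, j)) / rnode;
        vr(i, j) += dt / rhob * (dsrr + dsrz + hoop);
        vr(i, j) *= damp_r[i] * damp_z[j];
      }
    }
    for (int j = 1; j < nz; ++j) {
      for (int i = 0; i < nr; ++i) {
        double rhob = 0.5 * (rho(i, j - 1) + rho(i, j));
        double rc = (i + 0.5) * h;
        // (1/r) d(r srz)/dr with r srz = 0 on the axis
        double div_rz = ((i + 1) * h * srz(i + 1, j) - i * h * srz(i, j)) / (rc * h);
        double dszz = (szz(i, j) - szz(i, j - 1)) / h;
        vz(i, j) += dt / rhob * (div_rz + dszz);
        vz(i, j) *= damp_r[i] * damp_z[j];
      }
    }

    // --- stress update (uses velocities at time level n + 1/2) ---
    double src = src_series[n] * dt;
    for (int j = 0; j < nz; ++j) {
      for (int i = 0; i < nr; ++i) {
        double rc = (i + 0.5) * h;
        double err = (vr(i + 1, j) - vr(i, j)) / h;
        double ezz = (vz(i, j + 1) - vz(i, j)) / h;
        double ett = 0.5 * (vr(i + 1, j) + vr(i, j)) / rc;
        double lam = lambda(i, j), m2 = 2.0 * mu(i, j);
        double tr = err + ett + ezz;
        srr(i, j) += dt * (lam * tr + m2 * err);
        stt(i, j) += dt * (lam * tr + m2 * ett);
        szz(i, j) += dt * (lam * tr + m2 * ezz);
        double dmp = damp_r[i] * damp_z[j];
        srr(i, j) *= dmp; stt(i, j) *= dmp; szz(i, j) *= dmp;
      }
    }
    if (src != 0.0) {
      for (int q = 0; q < src_i.size(); ++q) {
        double ds = src * src_w[q];
        srr(src_i[q], src_j[q]) += ds;
        stt(src_i[q], src_j[q]) += ds;
        szz(src_i[q], src_j[q]) += ds;
      }
    }
    for (int j = 1; j < nz; ++j) {
      for (int i = 1; i < nr; ++i) {
        double m00 = mu(i - 1, j - 1), m10 = mu(i, j - 1), m01 = mu(i - 1, j), m11 = mu(i, j);
        double mh = 0.0;
        if (m00 > 0 && m10 > 0 && m01 > 0 && m11 > 0)
          mh = 4.0 / (1.0 / m00 + 1.0 / m10 + 1.0 / m01 + 1.0 / m11);
        if (mh > 0) {
          double dvr = (vr(i, j) - vr(i, j - 1)) / h;
          double dvz = (vz(i, j) - vz(i - 1, j)) / h;
          srz(i, j) += dt * mh * (dvr + dvz);
          srz(i, j) *= damp_r[i] * damp_z[j];
        } else {
          srz(i, j) = 0.0;
        }
      }
    }

    // --- records ---
    for (int k = 0; k < n_st; ++k) {
      int i = station_i[k], j = station_j[k];
      st_srr(n, k) = srr(i, j);
      st_stt(n, k) = stt(i, j);
      st_szz(n, k) = szz(i, j);
      st_srz(n, k) = 0.25 * (srz(i, j) + srz(i + 1, j) + srz(i, j + 1) + srz(i + 1, j + 1));
    }
    for (size_t q = 0; q < snap_at.size(); ++q) {
      if (snap_at[q] == n + 1) {
        NumericMatrix p(nr, nz);
        for (int j = 0; j < nz; ++j)
          for (int i = 0; i < nr; ++i)
            p(i, j) = -(srr(i, j) + stt(i, j) + szz(i, j)) / 3.0;
        snapshots.push_back(p);
      }
    }
    if (energy_every > 0 && (n + 1) % energy_every == 0) {
      double E = 0.0;
      for (int j = 0; j < nz; ++j) {
        for (int i = 0; i < nr; ++i) {
          double rc = (i + 0.5) * h;
          double vol = 2.0 * M_PI * rc * h * h;
          double vrb = 0.5 * (vr(i, j) + vr(i + 1, j));
          double vzb = 0.5 * (vz(i, j) + vz(i, j + 1));
          double kin = 0.5 * rho(i, j) * (vrb * vrb + vzb * vzb);
          double mmean = (srr(i, j) + stt(i, j) + szz(i, j)) / 3.0;
          double pot;
          if (mu(i, j) > 0) {
            double K = lambda(i, j) + 2.0 * mu(i, j) / 3.0;
            double s1 = srr(i, j) - mmean, s2 = stt(i, j) - mmean, s3 = szz(i, j) - mmean;
            double srzc = 0.25 * (srz(i, j) + srz(i + 1, j) + srz(i, j + 1) + srz(i + 1, j + 1));
            pot = (s1 * s1 + s2 * s2 + s3 * s3 + 2.0 * srzc * srzc) / (4.0 * mu(i, j)) +
                  mmean * mmean / (2.0 * K);
          } else {
            pot = mmean * mmean / (2.0 * lambda(i, j));
          }
          E += (kin + pot) * vol;
        }
      }
      energy.push_back(E);
    }
  }

  return List::create(_["snapshots"] = snapshots,
                      _["st_srr"] = st_srr, _["st_stt"] = st_stt,
                      _["st_szz"] = st_szz, _["st_srz"] = st_srz,
                      _["energy"] = wrap(energy));
}
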