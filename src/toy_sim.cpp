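#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Brownian-dynamics toy simulator with periodic orthorhombic
// boundaries. Pair interactions: a bounded-force soft-core potential
// (harmonic repulsion below the core diameter sigma, cosine-squared
// attractive well of species-pair depth eps between sigma and the
// range cutoff; C1-continuous, exactly zero beyond the cutoff), plus a
// truncated-and-shifted screened-Coulomb term for charged species. An
// optional time-dependent external field drives charged particles
// along one axis. Uses R's RNG (norm_rand) so runs are reproducible
// from set.seed().

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// [[Rcpp::export(name = ".run_toy_sim")]]
List run_toy_sim(NumericMatrix pos0, IntegerVector species_idx,
                 NumericMatrix eps, NumericVector charges,
                 NumericVector box, double dt, int n_steps,
                 double noise_amp, NumericVector field_drift,
                 int axis, double sigma_core, double cutoff,
                 double repulsion, double coulomb_strength, double kappa,
                 int sample_every, double d_max, double k_spatial,
                 double heat, double dt_heat) {
  const int n = pos0.nrow();
  const int ns = eps.nrow();
  const double cut2 = cutoff * cutoff;
  const double well_w = cutoff - sigma_core;  // attractive well width
  const double r_floor = 0.6 * sigma_core;  // Coulomb inner cap

  NumericMatrix pos = clone(pos0);
  NumericMatrix forces(n, 3);

  // shift so the screened-Coulomb term vanishes at the cutoff
  double coul_shift = std::exp(-kappa * cutoff) / cutoff;  // per unit qq*C

  const int n_samples = n_steps / sample_every + 1;
  const int npair = ns * (ns + 1) / 2;
  NumericMatrix lj_log(n_samples, npair);
  NumericMatrix coul_log(n_samples, npair);
  NumericVector t_log(n_samples);
  List frames(n_samples);

  int sample_i = 0;
  bool diverged = false;
  int diverge_step = -1;

  for (int step = 0; step <= n_steps; ++step) {
    // pair forces and (on sample steps) energies
    std::fill(forces.begin(), forces.end(), 0.0);
    bool sampling = (step % sample_every) == 0;
    std::vector<double> lj_acc(npair, 0.0), coul_acc(npair, 0.0);

    for (int i = 0; i < n - 1; ++i) {
      int si = species_idx[i];
      for (int j = i + 1; j < n; ++j) {
        int sj = species_idx[j];
        double dx = min_image(pos(i, 0) - pos(j, 0), box[0]);
        double dy = min_image(pos(i, 1) - pos(j, 1), box[1]);
        double dz = min_image(pos(i, 2) - pos(j, 2), box[2]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > cut2) continue;
        double r = std::sqrt(r2);
        double r_eff = (r < r_floor) ? r_floor : r;

        double e = eps(si, sj);
        double fr = 0.0;  // radial force, positive = repulsive
        double u_pair = 0.0;
        if (e == 0.0) {
          // eps = 0 switches the pair potential off entirely
        } else if (r < sigma_core) {
          // harmonic core, continued by the well floor: U = A(1-r/s)^2 - e
          double t = 1.0 - r / sigma_core;
          fr += 2.0 * repulsion * t / sigma_core;
          u_pair = repulsion * t * t - e;
        } else if (e != 0.0 && well_w > 0.0) {
          // cosine-squared well: U = -e cos^2(q), q = pi (r - s) / (2 w)
          double q = M_PI * (r - sigma_core) / (2.0 * well_w);
          double cq = std::cos(q);
          u_pair = -e * cq * cq;
          fr += -e * M_PI * std::sin(2.0 * q) / (2.0 * well_w);
        }
        if (sampling && (u_pair != 0.0)) {
          int a = si < sj ? si : sj, b = si < sj ? sj : si;
          int p = a * ns - a * (a - 1) / 2 + (b - a);
          lj_acc[p] += u_pair;
        }
        double qq = charges[i] * charges[j];
        if (qq != 0.0 && coulomb_strength != 0.0) {
          double ek = std::exp(-kappa * r_eff);
          // U = C qq exp(-kr)/r - shift; F_r = C qq ek (kr + 1) / r^2
          fr += coulomb_strength * qq * ek * (kappa * r_eff + 1.0) /
                (r_eff * r_eff);
          if (sampling) {
            int a = si < sj ? si : sj, b = si < sj ? sj : si;
            int p = a * ns - a * (a - 1) / 2 + (b - a);
            coul_acc[p] += coulomb_strength * qq * (ek / r_eff - coul_shift);
          }
        }
        if (fr != 0.0) {
          double inv_r = 1.0 / ((r < 1e-12) ? 1e-12 : r);
          double fx = fr * dx * inv_r;
          double fy = fr * dy * inv_r;
          double fz = fr * dz * inv_r;
          forces(i, 0) += fx; forces(i, 1) += fy; forces(i, 2) += fz;
          forces(j, 0) -= fx; forces(j, 1) -= fy; forces(j, 2) -= fz;
        }
      }
    }

    if (sampling) {
      t_log[sample_i] = step * dt;
      for (int p = 0; p < npair; ++p) {
        lj_log(sample_i, p) = lj_acc[p];
        coul_log(sample_i, p) = coul_acc[p];
      }
      frames[sample_i] = clone(pos);
      ++sample_i;
    }
    if (step == n_steps) break;

    // external field drift on charged particles, precomputed per step
    double drift = field_drift[step];

    for (int i = 0; i < n; ++i) {
      double fx = forces(i, 0) * dt;
      double fy = forces(i, 1) * dt;
      double fz = forces(i, 2) * dt;
      // displacement capping: steep-core excursions relax at bounded
      // speed instead of being launched across the box
      double fmag = std::sqrt(fx * fx + fy * fy + fz * fz);
      if (d_max > 0.0 && fmag > d_max) {
        double s = d_max / fmag;
        fx *= s; fy *= s; fz *= s;
      }
      if (std::fabs(fx) > box[0] / 2 || std::fabs(fy) > box[1] / 2 ||
          std::fabs(fz) > box[2] / 2) {
        diverged = true;
        diverge_step = step;
      }
      double move[3] = {fx, fy, fz};
      // standing-wave spatial phase (k_spatial = 0 gives a uniform
      // field); sine puts a node - the point of maximal differential
      // forcing - at the box centre, where the droplet inits sit
      double phase = (k_spatial != 0.0) ? std::sin(k_spatial * pos(i, axis))
                                        : 1.0;
      move[axis] += charges[i] * drift * phase * dt;
      // dissipative coupling: field work on a dragged charge heats its
      // local environment, raising the particle's effective temperature
      double v_drift = charges[i] * drift;
      double amp_i = (heat > 0.0 && v_drift != 0.0)
        ? std::sqrt(noise_amp * noise_amp +
                    2.0 * heat * v_drift * v_drift * dt_heat)
        : noise_amp;
      for (int ax = 0; ax < 3; ++ax) {
        double x = pos(i, ax) + move[ax] + amp_i * norm_rand();
        x -= box[ax] * std::floor(x / box[ax]);
        if (x >= box[ax]) x = 0.0;  // guard the pathological rounding case
        pos(i, ax) = x;
      }
    }
    if (diverged) break;
  }

  return List::create(
    Named("frames") = frames,
    Named("t_ps") = t_log,
    Named("lj") = lj_log,
    Named("coul") = coul_log,
    Named("n_samples") = sample_i,
    Named("diverged") = diverged,
    Named("diverge_step") = diverge_step);
}
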