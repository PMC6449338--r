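#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parametric membrane landscape shared with the R evaluators
// (R/membrane-model.R). Parameter vector layout:
//   0 amplitude  1 barrier_sd  2 well_depth  3 well_pos  4 well_sd
//   5 shift      6 D_bulk      7 D_core      8 D_sd
struct Landscape {
  double A, sb, d, zw, sw, shift, Dw, Dm, sD;
  explicit Landscape(const NumericVector &p)
      : A(p[0]), sb(p[1]), d(p[2]), zw(p[3]), sw(p[4]), shift(p[5]),
        Dw(p[6]), Dm(p[7]), sD(p[8]) {}
  inline double W(double z) const {
    double g = A * std::exp(-z * z / (2.0 * sb * sb));
    if (d != 0.0) {
      double zp = z - zw, zm = z + zw;
      g -= d * (std::exp(-zp * zp / (2.0 * sw * sw)) +
                std::exp(-zm * zm / (2.0 * sw * sw)));
    }
    return g - shift;
  }
  inline double dW(double z) const {
    double g = -A * z / (sb * sb) * std::exp(-z * z / (2.0 * sb * sb));
    if (d != 0.0) {
      double zp = z - zw, zm = z + zw;
      g += d * (zp / (sw * sw) * std::exp(-zp * zp / (2.0 * sw * sw)) +
                zm / (sw * sw) * std::exp(-zm * zm / (2.0 * sw * sw)));
    }
    return g;
  }
  inline double D(double z) const {
    return Dw - (Dw - Dm) * std::exp(-z * z / (2.0 * sD * sD));
  }
  inline double dD(double z) const {
    return (Dw - Dm) * z / (sD * sD) * std::exp(-z * z / (2.0 * sD * sD));
  }
};

// Overdamped Langevin step, Ito convention with the divergence (D')
// drift correction so the stationary density is Boltzmann even under
// position-dependent diffusivity:
//   dz = [-D (W' + k(z - z0)) / RT + D'] dt + sqrt(2 D dt) xi
// [[Rcpp::export]]
List simulate_window_cpp(NumericVector params, double z0, double ku,
                         double RT, double dt, int n_steps,
                         int equilibration_steps, int sample_stride) {
  Landscape m(params);
  int n_out = n_steps / sample_stride;
  NumericVector pos(n_out), frc(n_out);
  double z = z0;
  double sq = std::sqrt(2.0 * dt);
  RNGScope scope;
  for (int i = 0; i < equilibration_steps; ++i) {
    double Dz = m.D(z);
    z += (-Dz * (m.dW(z) + ku * (z - z0)) / RT + m.dD(z)) * dt +
         sq * std::sqrt(Dz) * norm_rand();
  }
  int j = 0;
  for (int i = 0; i < n_steps; ++i) {
    double Dz = m.D(z);
    z += (-Dz * (m.dW(z) + ku * (z - z0)) / RT + m.dD(z)) * dt +
         sq * std::sqrt(Dz) * norm_rand();
    if ((i + 1) % sample_stride == 0) {
      pos[j] = z;
      frc[j] = -m.dW(z) - ku * (z - z0);
      ++j;
    }
  }
  return List::create(_["position"] = pos, _["force"] = frc);
}

// First-passage times from `start` to the absorbing boundary with a
// reflecting boundary on the other side. Returns one passage time (ps)
// per particle; NA if max_steps is exhausted.
// [[Rcpp::export]]
NumericVector first_passage_cpp(NumericVector params, double RT, double dt,
                                double start, double absorbing,
                                double reflecting, int n_particles,
                                double max_steps) {
  Landscape m(params);
  NumericVector out(n_particles);
  double sq = std::sqrt(2.0 * dt);
  bool up = absorbing > reflecting;
  RNGScope scope;
  for (int p = 0; p < n_particles; ++p) {
    double z = start;
    double t = NA_REAL;
    for (double i = 0; i < max_steps; ++i) {
      double Dz = m.D(z);
      z += (-Dz * m.dW(z) / RT + m.dD(z)) * dt +
           sq * std::sqrt(Dz) * norm_rand();
      if (up) {
        if (z < reflecting) z = 2.0 * reflecting - z;
        if (z >= absorbing) { t = (i + 1) * dt; break; }
      } else {
        if (z > reflecting) z = 2.0 * reflecting - z;
        if (z <= absorbing) { t = (i + 1) * dt; break; }
      }
    }
    out[p] = t;
  }
  return out;
}
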