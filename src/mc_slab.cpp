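// Photon-transport Monte Carlo for a two-layer slab-on-half-space medium.
//
// Reduced (isotropic-scattering) random walk: free paths are exponential in
// the local reduced scattering coefficient, absorption is handled by
// continuous weight attenuation exp(-mua * l) along each segment, and the
// per-layer pathlengths of photons escaping through the top surface are
// tallied in annuli around the requested source-detector distances.
// The top boundary applies the unpolarised Fresnel reflectance for the
// refractive-index step; the internal interface is index-matched.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

static inline double fresnel_reflect(double cos_i, double n_in, double n_out) {
  // unpolarised reflectance from inside (n_in) towards outside (n_out)
  double sin_i2 = 1.0 - cos_i * cos_i;
  double m = n_out / n_in;
  if (sin_i2 >= m * m) return 1.0; // total internal reflection
  double sin_t2 = sin_i2 / (m * m);
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n_in * cos_i - n_out * cos_t) / (n_in * cos_i + n_out * cos_t);
  double rp = (n_in * cos_t - n_out * cos_i) / (n_in * cos_t + n_out * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

struct Tally {
  double sum_w = 0.0, sum_w2 = 0.0;
  double sum_wl1 = 0.0, sum_wl2 = 0.0;
  // accumulators for the ratio-estimator variances of L1, L2
  double sum_w2l1 = 0.0, sum_w2l2 = 0.0;   // sum w^2 l
  double sum_w2l1sq = 0.0, sum_w2l2sq = 0.0; // sum w^2 l^2
  long n_det = 0;
};

// [[Rcpp::export(name = ".mc_slab_cpp")]]
List mc_slab_cpp(double mua1, double musp1, double mua2, double musp2,
                 double d1, double n_in, double n_out,
                 NumericVector rho, double half_width,
                 double n_photons, int seed, double max_steps_d) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  const int nr = rho.size();
  std::vector<double> rlo(nr), rhi(nr), area(nr);
  for (int k = 0; k < nr; ++k) {
    rlo[k] = rho[k] - half_width;
    rhi[k] = rho[k] + half_width;
    area[k] = M_PI * (rhi[k] * rhi[k] - rlo[k] * rlo[k]);
  }
  const double wmin = 1e-4;       // roulette threshold
  const long   max_steps = static_cast<long>(max_steps_d);

  long n = static_cast<long>(n_photons);
  std::vector<Tally> tal(nr);
  double esc_w = 0.0;                        // all escaping weight

  for (long ip = 0; ip < n; ++ip) {
    double x = 0.0, y = 0.0, z = 1e-12;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0, l1 = 0.0, l2 = 0.0;
    bool alive = true;
    long steps = 0;

    while (alive && ++steps < max_steps) {
      double tau = -std::log(U(rng));        // scattering optical depth
      while (tau > 0.0) {
        int layer = (z < d1) ? 0 : 1;
        double musp = layer == 0 ? musp1 : musp2;
        double mua  = layer == 0 ? mua1  : mua2;
        double s_full = tau / musp;
        // distance to the nearest boundary along the current direction
        double s_b = INFINITY;
        int hit = 0; // 1 = top surface, 2 = internal interface
        if (uz < 0.0) {
          double s_top = -z / uz;
          double s_int = (layer == 1) ? (d1 - z) / uz : INFINITY;
          if (layer == 1 && s_int < s_top) { s_b = s_int; hit = 2; }
          else { s_b = s_top; hit = 1; }
        } else if (uz > 0.0 && layer == 0) {
          s_b = (d1 - z) / uz; hit = 2;
        }
        double s = std::min(s_full, s_b);
        x += ux * s; y += uy * s; z += uz * s;
        w *= std::exp(-mua * s);
        if (layer == 0) l1 += s; else l2 += s;
        if (s_full < s_b) {                  // scattering event
          tau = 0.0;
        } else {
          tau -= musp * s;
          if (hit == 1) {                    // top surface
            double ci = -uz;
            if (U(rng) < fresnel_reflect(ci, n_in, n_out)) {
              uz = -uz; z = 1e-12;
            } else {                         // escapes
              esc_w += w;
              double r = std::sqrt(x * x + y * y);
              for (int k = 0; k < nr; ++k) {
                if (r >= rlo[k] && r < rhi[k]) {
                  Tally &t = tal[k];
                  t.sum_w += w; t.sum_w2 += w * w;
                  t.sum_wl1 += w * l1; t.sum_wl2 += w * l2;
                  t.sum_w2l1 += w * w * l1; t.sum_w2l2 += w * w * l2;
                  t.sum_w2l1sq += w * w * l1 * l1;
                  t.sum_w2l2sq += w * w * l2 * l2;
                  ++t.n_det;
                  break;
                }
              }
              alive = false; tau = 0.0;
            }
          } else {                           // index-matched interface
            z = (uz > 0.0) ? d1 + 1e-12 : d1 - 1e-12;
          }
        }
      }
      if (!alive) break;
      // isotropic scattering
      double czz = 2.0 * U(rng) - 1.0;
      double szz = std::sqrt(std::max(0.0, 1.0 - czz * czz));
      double phi = 2.0 * M_PI * U(rng);
      ux = szz * std::cos(phi); uy = szz * std::sin(phi); uz = czz;
      // Russian roulette
      if (w < wmin) {
        if (U(rng) < 0.1) w *= 10.0; else alive = false;
      }
    }
  }

  NumericVector refl(nr), se_refl(nr), ndet(nr);
  NumericMatrix L(nr, 2), seL(nr, 2);
  for (int k = 0; k < nr; ++k) {
    Tally &t = tal[k];
    double R = t.sum_w / (static_cast<double>(n) * area[k]);
    refl[k] = R;
    double ex2 = t.sum_w2 / (static_cast<double>(n) * area[k] * area[k]);
    se_refl[k] = std::sqrt(std::max(0.0, ex2 - R * R) /
                           static_cast<double>(n));
    ndet[k] = static_cast<double>(t.n_det);
    if (t.n_det > 1 && t.sum_w > 0.0) {
      double L1 = t.sum_wl1 / t.sum_w, L2 = t.sum_wl2 / t.sum_w;
      // sum w^2 (l - Lbar)^2 expanded in the accumulated moments
      double v1 = t.sum_w2l1sq - 2.0 * L1 * t.sum_w2l1 + L1 * L1 * t.sum_w2;
      double v2 = t.sum_w2l2sq - 2.0 * L2 * t.sum_w2l2 + L2 * L2 * t.sum_w2;
      L(k, 0) = L1; L(k, 1) = L2;
      seL(k, 0) = std::sqrt(std::max(0.0, v1)) / t.sum_w;
      seL(k, 1) = std::sqrt(std::max(0.0, v2)) / t.sum_w;
    } else {
      L(k, 0) = NA_REAL; L(k, 1) = NA_REAL;
      seL(k, 0) = NA_REAL; seL(k, 1) = NA_REAL;
    }
  }
  return List::create(
    _["reflectance"] = refl, _["se_reflectance"] = se_refl,
    _["L"] = L, _["se_L"] = seL, _["n_detected"] = ndet,
    _["escaped_weight_fraction"] = esc_w / static_cast<double>(n));
}
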