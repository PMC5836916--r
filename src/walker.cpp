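#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: fast, reproducible stream fully
// determined by the 64-bit seed (independent of R's RNG state)
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      s[i] = x ^ (x >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

static inline void rand_dir(Xoshiro &rng, double d[3]) {
  // Marsaglia (1972) uniform direction on the unit sphere
  double u, v, s;
  do {
    u = 2.0 * rng.unif() - 1.0;
    v = 2.0 * rng.unif() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s == 0.0);
  double f = 2.0 * std::sqrt(1.0 - s);
  d[0] = u * f; d[1] = v * f; d[2] = 1.0 - 2.0 * s;
}

static inline double wrap1(double x, double L) {
  return x - L * std::floor(x / L + 0.5);
}

struct Geom {
  double r, r2, hh, lx, lz;
  bool membrane;
  inline bool intra(double x, double y, double z) const {
    if (!membrane) return false;
    x = wrap1(x, lx); y = wrap1(y, lx); z = wrap1(z, lz);
    return (x * x + y * y <= r2) && (std::fabs(z) <= hh);
  }
  // shortest distance to the cylinder surface; valid near the membrane
  // (within one step), where the primary image is always the nearest one
  inline double dist_membrane(double x, double y, double z) const {
    x = wrap1(x, lx); y = wrap1(y, lx); z = wrap1(z, lz);
    double rho = std::sqrt(x * x + y * y);
    double drho = rho - r;
    double dz = std::fabs(z) - hh;
    if (drho > 0.0 && dz > 0.0) return std::sqrt(drho * drho + dz * dz);
    if (drho > 0.0) return drho;
    if (dz > 0.0) return dz;
    return std::min(-drho, -dz);
  }
};

// [[Rcpp::export]]
List walk_cpp(double cyl_radius, double half_height, double cell_xy,
              double cell_z, bool membrane, double f_intra,
              double kappa_e, double kappa_p, double D_p, double D_e,
              double ds_p, double ds_e, double dt, int n_steps,
              int n_particles, List profile_bounds, double seed) {
  Geom geo;
  geo.r = cyl_radius;
  geo.r2 = cyl_radius * cyl_radius;
  geo.hh = half_height;
  geo.lx = cell_xy;
  geo.lz = cell_z;
  geo.membrane = membrane;

  const int n_prof = profile_bounds.size();
  std::vector<std::vector<int> > bounds(n_prof);
  std::vector<int> nK(n_prof);
  for (int p = 0; p < n_prof; ++p) {
    IntegerVector b = profile_bounds[p];
    bounds[p] = std::vector<int>(b.begin(), b.end());
    nK[p] = b.size() - 1;
  }

  // outputs
  List xcm_out(n_prof);
  std::vector<double *> xcm_ptr(n_prof);
  for (int p = 0; p < n_prof; ++p) {
    NumericVector a(Dimension(n_particles, nK[p], 3));
    xcm_out[p] = a;
    xcm_ptr[p] = REAL(a);
  }
  LogicalVector start_intra(n_particles), end_intra(n_particles);
  NumericVector frac_intra(n_particles), first_exit(n_particles, NA_REAL);
  NumericMatrix disp(n_particles, 3);

  Xoshiro rng((uint64_t)seed);

  // transmission P = 2 d_s kappa_i / D_i with d_s the distance from the
  // pre-step position to the membrane; averaging the attempt rate over a
  // step-length-deep layer makes the realized wall permeability equal
  // kappa_i exactly for this fixed-step scheme
  const double P_coef_e = 2.0 * kappa_e / D_e;
  const double P_coef_p = 2.0 * kappa_p / D_p;

  // per-particle interval accumulators, laid out profile-major
  std::vector<int> off_acc(n_prof);
  int acc_len = 0;
  for (int q = 0; q < n_prof; ++q) { off_acc[q] = acc_len; acc_len += nK[q] * 3; }
  std::vector<double> acc(acc_len);

  for (int i = 0; i < n_particles; ++i) {
    // initial position: intracellular with probability f, uniform within
    // the chosen compartment (water-concentration weighting)
    double p[3];
    bool cur;
    if (membrane && rng.unif() < f_intra) {
      double rho = cyl_radius * std::sqrt(rng.unif());
      double th = 2.0 * M_PI * rng.unif();
      p[0] = rho * std::cos(th);
      p[1] = rho * std::sin(th);
      p[2] = half_height * (2.0 * rng.unif() - 1.0);
      cur = true;
    } else {
      do {
        p[0] = cell_xy * (rng.unif() - 0.5);
        p[1] = cell_xy * (rng.unif() - 0.5);
        p[2] = cell_z * (rng.unif() - 0.5);
      } while (geo.intra(p[0], p[1], p[2]));
      cur = false;
    }
    start_intra[i] = cur;
    double off[3] = {0.0, 0.0, 0.0};
    double x0[3] = {p[0], p[1], p[2]};
    long n_intra = 0;
    double t_exit = NA_REAL;
    bool exited = !cur;

    // reset accumulators and per-profile interval pointers
    std::fill(acc.begin(), acc.end(), 0.0);
    std::vector<int> cursor(n_prof, 0);

    for (int j = 1; j <= n_steps; ++j) {
      double dir[3];
      rand_dir(rng, dir);
      double remaining = cur ? ds_e : ds_p;
      for (int it = 0; it < 10 && remaining > 0.0; ++it) {
        double tx = p[0] + remaining * dir[0];
        double ty = p[1] + remaining * dir[1];
        double tz = p[2] + remaining * dir[2];
        bool tgt = geo.intra(tx, ty, tz);
        if (tgt == cur) {
          p[0] = tx; p[1] = ty; p[2] = tz;
          remaining = 0.0;
          break;
        }
        // bisect the segment for the membrane crossing
        double slo = 0.0, shi = 1.0;
        for (int bs = 0; bs < 30; ++bs) {
          double sm = 0.5 * (slo + shi);
          bool m = geo.intra(p[0] + sm * remaining * dir[0],
                             p[1] + sm * remaining * dir[1],
                             p[2] + sm * remaining * dir[2]);
          if (m == cur) slo = sm; else shi = sm;
        }
        double clo[3] = {p[0] + slo * remaining * dir[0],
                         p[1] + slo * remaining * dir[1],
                         p[2] + slo * remaining * dir[2]};
        double chi[3] = {p[0] + shi * remaining * dir[0],
                         p[1] + shi * remaining * dir[1],
                         p[2] + shi * remaining * dir[2]};
        double d_s = geo.dist_membrane(p[0], p[1], p[2]);
        double P = std::min(1.0, (cur ? P_coef_e : P_coef_p) * d_s);
        if (rng.unif() < P) {
          // transmit: continue into the other compartment, residual path
          // rescaled by the destination step length
          double used = shi * remaining;
          double rest = remaining - used;
          remaining = rest * (cur ? (ds_p / ds_e) : (ds_e / ds_p));
          p[0] = chi[0]; p[1] = chi[1]; p[2] = chi[2];
          if (cur && !exited) { t_exit = j * dt; exited = true; }
          cur = !cur;
        } else {
          // specular reflection at the crossing point
          double wx = wrap1(clo[0], cell_xy);
          double wy = wrap1(clo[1], cell_xy);
          double wz = wrap1(clo[2], cell_z);
          double rho = std::sqrt(wx * wx + wy * wy);
          double d_lat = std::fabs(rho - cyl_radius);
          double d_cap = std::fabs(std::fabs(wz) - half_height);
          double n[3];
          if (d_lat < d_cap && rho > 0.0) {
            n[0] = wx / rho; n[1] = wy / rho; n[2] = 0.0;
          } else {
            n[0] = 0.0; n[1] = 0.0; n[2] = (wz >= 0.0 ? 1.0 : -1.0);
          }
          double dn = dir[0] * n[0] + dir[1] * n[1] + dir[2] * n[2];
          dir[0] -= 2.0 * dn * n[0];
          dir[1] -= 2.0 * dn * n[1];
          dir[2] -= 2.0 * dn * n[2];
          remaining -= slo * remaining;
          p[0] = clo[0]; p[1] = clo[1]; p[2] = clo[2];
        }
      }
      // wrap into the primary cell, keeping the unwrapped offset
      for (int c = 0; c < 3; ++c) {
        double L = (c == 2) ? cell_z : cell_xy;
        double w = wrap1(p[c], L);
        off[c] += p[c] - w;
        p[c] = w;
      }
      if (cur) ++n_intra;
      // accumulate unwrapped position into the active interval per profile
      for (int q = 0; q < n_prof; ++q) {
        const std::vector<int> &b = bounds[q];
        int &k = cursor[q];
        while (k < nK[q] && j > b[k + 1]) ++k;
        if (k < nK[q] && j > b[k] && j <= b[k + 1]) {
          double *a = &acc[off_acc[q] + k * 3];
          a[0] += p[0] + off[0];
          a[1] += p[1] + off[1];
          a[2] += p[2] + off[2];
        }
      }
    }

    end_intra[i] = cur;
    frac_intra[i] = (double)n_intra / (double)n_steps;
    first_exit[i] = t_exit;
    for (int c = 0; c < 3; ++c) disp(i, c) = p[c] + off[c] - x0[c];
    for (int q = 0; q < n_prof; ++q) {
      const std::vector<int> &b = bounds[q];
      double *out = xcm_ptr[q];
      for (int k = 0; k < nK[q]; ++k) {
        double cnt = (double)(b[k + 1] - b[k]);
        for (int c = 0; c < 3; ++c)
          out[i + n_particles * (k + nK[q] * c)] =
            acc[off_acc[q] + k * 3 + c] / cnt;
      }
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["x_cm"] = xcm_out,
    _["start_intra"] = start_intra,
    _["end_intra"] = end_intra,
    _["frac_intra"] = frac_intra,
    _["first_exit_ms"] = first_exit,
    _["displacement"] = disp);
}
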