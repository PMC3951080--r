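// Condensed-history charged-particle stepping in a rectilinear voxel grid.
//
// Physics tables arrive pre-computed from R on a uniform log-energy grid
// per material: mass collision stopping power (MeV cm^2/g), mass CSDA
// range (g/cm^2) and, for electrons, mass radiative stopping power.
// Within a step the medium is the voxel at the step's start; steps are
// limited by a fraction of the smallest voxel spacing, a fraction of the
// residual CSDA range, and the distance to the next voxel boundary, so a
// step never spans more than one voxel (deposits split across voxels by
// construction).  Uses R's RNG so batch seeding from R is reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Tables {
  int nk, nmat;
  double loge0, dloge;
  const double *logS, *logR, *logSrad; // nk x nmat, column-major
  const double *X0, *refdens;          // per material
  const double *ZA;
};

static inline double interp_col(const double *tab, int nk, int m,
                                double loge, double loge0, double dloge) {
  double u = (loge - loge0) / dloge;
  if (u <= 0) u = 0;
  if (u >= nk - 1) u = nk - 1 - 1e-9;
  int i = (int)u;
  double f = u - i;
  const double *col = tab + (size_t)m * nk;
  return std::exp(col[i] * (1 - f) + col[i + 1] * f);
}

// truncated standard normal (+-3 sigma), resampled
static inline double norm3() {
  double z;
  do { z = norm_rand(); } while (std::fabs(z) > 3.0);
  return z;
}

// [[Rcpp::export(name = ".transport_batch_cpp")]]
NumericVector transport_batch_cpp(
    NumericMatrix primaries,     // n x 8: x y z ux uy uz E weight
    IntegerVector dims, NumericVector spacing, NumericVector origin,
    IntegerVector mat_index,     // 0-based, length prod(dims)
    NumericVector density,
    NumericVector loge,          // shared knots (uniform)
    NumericMatrix logS, NumericMatrix logR, NumericMatrix logSrad,
    NumericVector ZA, NumericVector X0, NumericVector refdens,
    double max_step_frac_voxel, double max_step_frac_range,
    double cutoff, double mass_mev,
    bool do_straggle, bool do_scatter, bool do_radiative,
    double nuclear_kappa) {

  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double gx = nx * sx, gy = ny * sy, gz = nz * sz;
  const int nk = loge.size();
  const double loge0 = loge[0];
  const double dloge = loge[1] - loge[0];
  const double min_sp = std::min(sx, std::min(sy, sz));
  const double vox_cap = max_step_frac_voxel * min_sp;
  const double eps = 1e-6 * min_sp;
  const double bohr_k = 0.1569; // MeV^2 cm^2/g, z = 1

  NumericVector edep((size_t)nx * ny * nz);
  RNGScope scope;

  const int n = primaries.nrow();
  for (int ip = 0; ip < n; ++ip) {
    double x = primaries(ip, 0), y = primaries(ip, 1), z = primaries(ip, 2);
    double ux = primaries(ip, 3), uy = primaries(ip, 4), uz = primaries(ip, 5);
    double E = primaries(ip, 6);
    double w = primaries(ip, 7);
    if (E <= 0) continue;

    // if outside, advance to the grid entry point (vacuum outside)
    {
      double t0 = 0.0, t1 = 1e300;
      bool miss = false;
      double p[3] = {x, y, z}, d[3] = {ux, uy, uz};
      double lo[3] = {ox, oy, oz}, hi[3] = {ox + gx, oy + gy, oz + gz};
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(d[a]) < 1e-12) {
          if (p[a] <= lo[a] || p[a] >= hi[a]) { miss = true; break; }
        } else {
          double ta = (lo[a] - p[a]) / d[a], tb = (hi[a] - p[a]) / d[a];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 > t1) { miss = true; break; }
        }
      }
      if (miss) continue;
      if (t0 > 0) { x += (t0 + eps) * ux; y += (t0 + eps) * uy; z += (t0 + eps) * uz; }
    }

    bool alive = true;
    while (alive) {
      int ix = (int)std::floor((x - ox) / sx);
      int iy = (int)std::floor((y - oy) / sy);
      int iz = (int)std::floor((z - oz) / sz);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
        break; // left the grid
      size_t v = (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz);
      int m = mat_index[v];
      double rho = density[v];

      double S = interp_col(&logS(0, 0), nk, m, std::log(E), loge0, dloge) * rho;
      double Rres = interp_col(&logR(0, 0), nk, m, std::log(E), loge0, dloge) / rho;

      if (E <= cutoff) { edep[v] += w * E; break; }

      // distance to the next voxel boundary along the direction
      double tb = 1e300;
      if (ux > 1e-12)       tb = std::min(tb, (ox + (ix + 1) * sx - x) / ux);
      else if (ux < -1e-12) tb = std::min(tb, (ox + ix * sx - x) / ux);
      if (uy > 1e-12)       tb = std::min(tb, (oy + (iy + 1) * sy - y) / uy);
      else if (uy < -1e-12) tb = std::min(tb, (oy + iy * sy - y) / uy);
      if (uz > 1e-12)       tb = std::min(tb, (oz + (iz + 1) * sz - z) / uz);
      else if (uz < -1e-12) tb = std::min(tb, (oz + iz * sz - z) / uz);
      if (tb < 0) tb = 0;

      double step = vox_cap;
      double rng_cap = max_step_frac_range * Rres;
      if (rng_cap < step) step = rng_cap;
      if (Rres < step) step = Rres;
      bool crossed = false;
      if (tb + eps < step) { step = tb + eps; crossed = true; }
      if (step < eps) step = eps;

      // energy loss over the step (medium of the starting voxel)
      double dE = S * step;
      if (do_straggle) {
        double sigE = std::sqrt(bohr_k * ZA[m] * rho * step);
        dE += sigE * norm3();
      }
      if (dE < 0) dE = 0;
      double dErad = 0.0;
      if (do_radiative) {
        double srad = interp_col(&logSrad(0, 0), nk, m, std::log(E), loge0, dloge);
        if (srad > 1e-200) dErad = srad * rho * step;
      }
      double dtot = dE + dErad;
      if (dtot > E) { // clamp, keep the collision/radiative split
        double f = E / dtot;
        dE *= f; dErad *= f; dtot = E;
      }
      edep[v] += w * dE;           // radiative part leaves the system
      E -= dtot;

      // optional nuclear attenuation (protons): water-equivalent depth
      if (nuclear_kappa > 0) {
        double rho_rel = rho; // relative to water (1 g/cm^3)
        if (unif_rand() > std::exp(-nuclear_kappa * rho_rel * step))
          break; // particle removed, no local deposit
      }

      x += step * ux; y += step * uy; z += step * uz;

      if (E <= cutoff) {
        // deposit the residual locally, in the voxel now containing the
        // particle (or the last one if it just left)
        int jx = (int)std::floor((x - ox) / sx);
        int jy = (int)std::floor((y - oy) / sy);
        int jz = (int)std::floor((z - oz) / sz);
        size_t vv = v;
        if (jx >= 0 && jx < nx && jy >= 0 && jy < ny && jz >= 0 && jz < nz)
          vv = (size_t)jx + (size_t)nx * ((size_t)jy + (size_t)ny * jz);
        edep[vv] += w * E;
        break;
      }

      if (do_scatter) {
        double kin = E;
        double pc = std::sqrt(kin * (kin + 2 * mass_mev));
        double beta = pc / (kin + mass_mev);
        double t = step * rho / X0[m];
        double bracket = 1 + 0.038 * std::log(t);
        if (bracket < 0.25) bracket = 0.25;
        double sig = 13.6 / (beta * pc) * std::sqrt(t) * bracket;
        double t1 = sig * norm_rand(), t2 = sig * norm_rand();
        // orthonormal frame perpendicular to the direction
        double ax = 0, ay = 0, az = 1;
        if (std::fabs(uz) > 0.9) { ax = 1; az = 0; }
        double e1x = uy * az - uz * ay, e1y = uz * ax - ux * az, e1z = ux * ay - uy * ax;
        double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
        e1x /= n1; e1y /= n1; e1z /= n1;
        double e2x = uy * e1z - uz * e1y, e2y = uz * e1x - ux * e1z, e2z = ux * e1y - uy * e1x;
        ux += t1 * e1x + t2 * e2x;
        uy += t1 * e1y + t2 * e2y;
        uz += t1 * e1z + t2 * e2z;
        double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= nn; uy /= nn; uz /= nn;
      }
      (void)crossed;
    }
  }
  return edep;
}
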