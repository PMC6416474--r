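// Voxel-based Monte Carlo photon transport for turbid media.
//
// Geometry: rectangular grid of cubic voxels, edge h (cm); voxel (i,j,k)
// spans [i*h,(i+1)*h) x ... (0-based, half-open); z = 0 is the illuminated
// face and z grows with depth.  A collimated disc source in air points along
// +z through the lateral grid centre.  Transport follows the MCML lineage:
// exponential free paths in dimensionless optical depth (so a path crossing
// into a voxel with different mu_s is rescaled automatically), continuous
// absorption weighting exp(-mu_a * l) deposited voxel by voxel, and
// Henyey-Greenstein scattering.  Exterior faces see unpolarized Fresnel
// reflection against air (n = 1); escapes through z = 0 are tallied as
// diffuse reflectance, all other faces as transmittance.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: one splitmix64 stream per photon, keyed on (seed, id).
// Stateless across photons, so results do not depend on scheduling order.
// ---------------------------------------------------------------------------
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t s) : state(s) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0, 1]: never returns 0 so -log(u) is finite
  double u_open0() {
    return (static_cast<double>(next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // uniform on [0, 1)
  double u_open1() {
    return static_cast<double>(next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

static inline uint64_t mix_key(uint64_t seed, uint64_t id) {
  // SplitMix64 finalizer applied to the pair; decorrelates nearby ids
  uint64_t z = seed * 0x9E3779B97F4A7C15ULL + id;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// ---------------------------------------------------------------------------
// Unpolarized Fresnel reflectance, average of s and p intensities.
// ---------------------------------------------------------------------------
static double fresnel_R(double n1, double n2, double cos_i) {
  if (cos_i > 1.0) cos_i = 1.0;
  if (n1 == n2) return 0.0;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  if (cos_i > 0.99999) {  // normal incidence limit of the amplitude formulas
    double r = (n1 - n2) / (n1 + n2);
    return r * r;
  }
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
NumericVector cpp_fresnel_unpolarized(NumericVector n1, NumericVector n2,
                                      NumericVector cos_theta_i) {
  R_xlen_t n = std::max(std::max(n1.size(), n2.size()), cos_theta_i.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = fresnel_R(n1[i % n1.size()], n2[i % n2.size()],
                       cos_theta_i[i % cos_theta_i.size()]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Henyey-Greenstein deflection cosine from a uniform deviate.
// ---------------------------------------------------------------------------
static inline double hg_cos(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// [[Rcpp::export]]
NumericVector cpp_hg_sample(double g, NumericVector u) {
  NumericVector out(u.size());
  for (R_xlen_t i = 0; i < u.size(); ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Direction update: rotate by deflection cosine ct and azimuth phi about the
// current direction (standard MCML spin).
// ---------------------------------------------------------------------------
static inline void spin(double ct, double phi, double& ux, double& uy,
                        double& uz) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nuz = -st * cp * den + uz * ct;
    ux = nux; uy = nuy; uz = nuz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

struct Tally {
  double specular = 0, diffuse = 0, transmitted = 0;
  double killed = 0, injected = 0;  // Russian-roulette weight ledger
};

// Deposition record for single-photon tracing
struct Deposit {
  int voxel;
  double w;
};

// ---------------------------------------------------------------------------
// Propagate one photon.  `A` receives absorbed weight (or track length in
// voxels with mu_a == 0).  Returns nothing; tallies go to `tal`, optional
// per-voxel trace to `trace`.
// ---------------------------------------------------------------------------
static void propagate(SplitMix64& rng, double x, double y,
                      int nx, int ny, int nz, double h,
                      const int* pidx, const double* mua, const double* mus,
                      const double* gg, const double* nn,
                      double wth, bool roulette, double* A, Tally& tal,
                      std::vector<Deposit>* trace) {
  // entry voxel
  int ix = static_cast<int>(std::floor(x / h));
  int iy = static_cast<int>(std::floor(y / h));
  int iz = 0;
  if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) return;  // misses the grid

  int v = ix + nx * (iy + ny * iz);
  double n_in = nn[pidx[v]];

  // specular reflection at the air -> tissue interface (normal incidence)
  double Rsp = fresnel_R(1.0, n_in, 1.0);
  tal.specular += Rsp;
  double w = 1.0 - Rsp;

  double ux = 0.0, uy = 0.0, uz = 1.0;
  // reciprocal direction components, refreshed after every redirection
  double rx = 1e30, ry = 1e30, rz = 1.0;
  double z = 0.0;
  double s = -std::log(rng.u_open0());  // dimensionless scattering depth

  const double INF = 1e30;
  for (;;) {
    int p = pidx[v];
    double ma = mua[p], ms = mus[p];

    // distance to the next voxel face along each axis
    double tx = INF, ty = INF, tz = INF;
    if (ux > 0)      tx = ((ix + 1) * h - x) * rx;
    else if (ux < 0) tx = (ix * h - x) * rx;
    if (uy > 0)      ty = ((iy + 1) * h - y) * ry;
    else if (uy < 0) ty = (iy * h - y) * ry;
    if (uz > 0)      tz = ((iz + 1) * h - z) * rz;
    else if (uz < 0) tz = (iz * h - z) * rz;

    int axis = 0; double db = tx;
    if (ty < db) { db = ty; axis = 1; }
    if (tz < db) { db = tz; axis = 2; }
    if (db < 0) db = 0;

    double ds = s / ms;
    bool hit_boundary = db <= ds;
    double t = hit_boundary ? db : ds;

    // absorb along the sub-path
    if (ma > 0) {
      double att = std::exp(-ma * t);
      double dw = w * (1.0 - att);
      A[v] += dw;
      if (trace) trace->push_back({v, dw});
      w *= att;
    } else {
      A[v] += w * t;  // track-length tally, converted to fluence later
      if (trace) trace->push_back({v, 0.0});
    }
    s -= t * ms;
    x += t * ux; y += t * uy; z += t * uz;

    if (hit_boundary) {
      // snap to the face to avoid floating-point drift
      int step;
      if (axis == 0) {
        step = ux > 0 ? 1 : -1;
        x = (ix + (step > 0 ? 1 : 0)) * h;
      } else if (axis == 1) {
        step = uy > 0 ? 1 : -1;
        y = (iy + (step > 0 ? 1 : 0)) * h;
      } else {
        step = uz > 0 ? 1 : -1;
        z = (iz + (step > 0 ? 1 : 0)) * h;
      }
      int jx = ix + (axis == 0 ? step : 0);
      int jy = iy + (axis == 1 ? step : 0);
      int jz = iz + (axis == 2 ? step : 0);
      bool outside = jx < 0 || jx >= nx || jy < 0 || jy >= ny ||
                     jz < 0 || jz >= nz;
      if (outside) {
        double cos_i = (axis == 0) ? std::fabs(ux)
                     : (axis == 1) ? std::fabs(uy) : std::fabs(uz);
        double R = fresnel_R(nn[p], 1.0, cos_i);
        if (rng.u_open1() < R) {
          // internal reflection: flip the crossing component
          if (axis == 0) { ux = -ux; rx = -rx; }
          else if (axis == 1) { uy = -uy; ry = -ry; }
          else { uz = -uz; rz = -rz; }
        } else {
          if (axis == 2 && step < 0) tal.diffuse += w;
          else tal.transmitted += w;
          return;
        }
      } else {
        ix = jx; iy = jy; iz = jz;
        v = ix + nx * (iy + ny * iz);
        // s is optical depth, so the new voxel's mu_s rescales the free
        // path automatically on the next iteration
      }
    } else {
      // scattering event
      double ct = hg_cos(gg[p], rng.u_open1());
      double phi = 6.283185307179586 * rng.u_open1();
      spin(ct, phi, ux, uy, uz);
      rx = ux != 0 ? 1.0 / ux : 1e30;
      ry = uy != 0 ? 1.0 / uy : 1e30;
      rz = uz != 0 ? 1.0 / uz : 1e30;
      s = -std::log(rng.u_open0());
    }

    if (w < wth) {
      if (roulette) {
        if (rng.u_open1() < 0.1) {
          tal.injected += 9.0 * w;
          w *= 10.0;
        } else {
          tal.killed += w;
          return;
        }
      } else {
        tal.killed += w;
        return;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_run_mc(IntegerVector dims, double h, IntegerVector property_index,
                NumericMatrix props, double beam_radius, double n_photons_d,
                double seed_d, double weight_threshold, bool roulette) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  if (property_index.size() != nvox)
    stop("property index length does not match grid dimensions");

  int np = props.nrow();
  std::vector<double> mua(np), mus(np), gg(np), nn(np);
  for (int i = 0; i < np; ++i) {
    mua[i] = props(i, 0); mus[i] = props(i, 1);
    gg[i] = props(i, 2);  nn[i] = props(i, 3);
  }

  NumericVector A(nvox);  // absorbed weight (or track length where mu_a = 0)
  Tally tal;
  double cx = 0.5 * nx * h, cy = 0.5 * ny * h;
  uint64_t seed = static_cast<uint64_t>(seed_d);
  uint64_t n_photons = static_cast<uint64_t>(n_photons_d);

  for (uint64_t i = 0; i < n_photons; ++i) {
    SplitMix64 rng(mix_key(seed, i));
    double r = beam_radius * std::sqrt(rng.u_open1());
    double th = 6.283185307179586 * rng.u_open1();
    propagate(rng, cx + r * std::cos(th), cy + r * std::sin(th),
              nx, ny, nz, h, property_index.begin(),
              mua.data(), mus.data(), gg.data(), nn.data(),
              weight_threshold, roulette, REAL(A), tal, nullptr);
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  double absorbed_w = 0;
  for (R_xlen_t v = 0; v < nvox; ++v)
    if (mua[property_index[v]] > 0) absorbed_w += A[v];

  return List::create(
    _["absorbed"] = A,
    _["specular"] = tal.specular / n_photons_d,
    _["diffuse"] = tal.diffuse / n_photons_d,
    _["transmitted"] = tal.transmitted / n_photons_d,
    _["absorbed_deposited"] = absorbed_w / n_photons_d,
    _["roulette_killed"] = tal.killed / n_photons_d,
    _["roulette_injected"] = tal.injected / n_photons_d);
}

// Single-photon trace: per-voxel deposition list, for determinism checks
// and debugging.  Photon `photon_id` of the stream keyed by `seed`.
// [[Rcpp::export]]
List cpp_trace_photon(IntegerVector dims, double h,
                      IntegerVector property_index, NumericMatrix props,
                      double beam_radius, double seed_d, double photon_id,
                      double weight_threshold, bool roulette) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int np = props.nrow();
  std::vector<double> mua(np), mus(np), gg(np), nn(np);
  for (int i = 0; i < np; ++i) {
    mua[i] = props(i, 0); mus[i] = props(i, 1);
    gg[i] = props(i, 2);  nn[i] = props(i, 3);
  }
  R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector A(nvox);
  Tally tal;
  std::vector<Deposit> trace;
  double cx = 0.5 * nx * h, cy = 0.5 * ny * h;
  SplitMix64 rng(mix_key(static_cast<uint64_t>(seed_d),
                         static_cast<uint64_t>(photon_id)));
  double r = beam_radius * std::sqrt(rng.u_open1());
  double th = 6.283185307179586 * rng.u_open1();
  propagate(rng, cx + r * std::cos(th), cy + r * std::sin(th),
            nx, ny, nz, h, property_index.begin(),
            mua.data(), mus.data(), gg.data(), nn.data(),
            weight_threshold, roulette, REAL(A), tal, &trace);

  int nrec = trace.size();
  IntegerVector vox(nrec);
  NumericVector dep(nrec);
  for (int i = 0; i < nrec; ++i) {
    vox[i] = trace[i].voxel + 1;  // 1-based for R
    dep[i] = trace[i].w;
  }
  return List::create(_["voxel"] = vox, _["deposit"] = dep,
                      _["specular"] = tal.specular,
                      _["diffuse"] = tal.diffuse,
                      _["transmitted"] = tal.transmitted);
}
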