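// Photon-packet Monte Carlo kernel for the reflective-PPG phantom scene.
//
// Geometry (all lengths mm): origin at the phantom surface midpoint between
// the source and detector spots, +z pointing INTO the phantom, +x from the
// source spot toward the detector spot.  Above the surface (z < 0) sits an
// air gap, a 1 mm glass slide layer and the opaque optical barrier centred
// at x = 0; the phantom is a homogeneous scattering half-cylinder below.
//
// Transport: free paths are sampled as dimensionless optical depth
// tau = -log(u); leftover tau is carried across interfaces.  Scattering and
// discrete absorption weighting (dw = w * mua/mut) happen only in the
// phantom; glass is attenuated by Lambert-Beer along the traversed chord;
// air layers are lossless.  Interfaces use statistical Fresnel
// reflect/refract with unpolarized reflectance; the barrier absorbs on
// entry.  Low-weight packets undergo Russian roulette.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// xoshiro256++ seeded via splitmix64; one independent stream per
// (seed, stream) pair, bitwise reproducible across platforms.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

static inline uint64_t stream_key(int seed, int stream) {
  return (uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL +
         (uint64_t)(uint32_t)stream * 0xBF58476D1CE4E5B9ULL + 0xD1B54A32D192ED03ULL;
}

// ---------------------------------------------------------- materials ----
enum Mat { AMB = 0, PH = 1, GLASS = 2, GAP = 3, BARRIER = 4 };

struct Scene {
  double gap_t, glass_t;      // thicknesses [mm]
  double z1, z2;              // z1 = -gap_t (gap/glass), z2 = -(gap_t+glass_t) (glass top)
  double barrier_half;        // half thickness in x
  double barrier_top;         // z of barrier top (<= 0); barrier spans [barrier_top, 0)
  bool   barrier_on;
  double radius, height, R2;
  double n[5];                // refractive index per material
  double mua[5];              // absorption per material [1/mm]
  double mus_p, mut_p;        // phantom scattering / total interaction
};

static inline int material_of(const Scene &sc, double x, double y, double z) {
  if (z >= 0.0) {
    if (z <= sc.height && x * x + y * y <= sc.R2) return PH;
    return AMB;
  }
  if (sc.barrier_on && std::fabs(x) <= sc.barrier_half && z >= sc.barrier_top)
    return BARRIER;
  if (z >= sc.z1) return (x * x + y * y <= sc.R2) ? GAP : AMB;
  if (z >= sc.z2) return (x * x + y * y <= sc.R2) ? GLASS : AMB;
  return AMB;
}

// surface ids: 0 z=0, 1 z=z1, 2 z=z2, 3 z=barrier_top, 4 z=height,
//              5 x=+bh, 6 x=-bh, 7 cylinder
struct Hit { double t; int surf; };

static const double TMIN = 1e-9;
static const double PUSH = 1e-7;
static const double INF_T = 1e30;

static inline void plane_hit(double z, double dz, double zp, int id, Hit &best) {
  if (dz == 0.0) return;
  double t = (zp - z) / dz;
  if (t > TMIN && t < best.t) { best.t = t; best.surf = id; }
}

// cylinder r = radius, restricted to z in [0, height]
static inline void cyl_hit(const Scene &sc, double x, double y, double z,
                           double dx, double dy, double dz, Hit &best) {
  double a = dx * dx + dy * dy;
  if (a < 1e-16) return;
  double b = x * dx + y * dy;
  double c = x * x + y * y - sc.R2;
  double disc = b * b - a * c;
  if (disc <= 0.0) return;
  double sq = std::sqrt(disc);
  for (int i = 0; i < 2; ++i) {
    double t = (i == 0) ? (-b - sq) / a : (-b + sq) / a;
    if (t > TMIN && t < best.t) {
      double zh = z + t * dz;
      if (zh >= 0.0 && zh <= sc.height) { best.t = t; best.surf = 7; }
    }
  }
}

// nearest boundary from inside the phantom (hot path: only 3 surfaces)
static inline Hit phantom_boundary(const Scene &sc, double x, double y, double z,
                                   double dx, double dy, double dz) {
  Hit best; best.t = INF_T; best.surf = -1;
  plane_hit(z, dz, 0.0, 0, best);
  plane_hit(z, dz, sc.height, 4, best);
  cyl_hit(sc, x, y, z, dx, dy, dz, best);
  return best;
}

// nearest boundary anywhere (non-scattering media)
static inline Hit any_boundary(const Scene &sc, double x, double y, double z,
                               double dx, double dy, double dz) {
  Hit best; best.t = INF_T; best.surf = -1;
  plane_hit(z, dz, 0.0, 0, best);
  if (sc.gap_t > 0.0) plane_hit(z, dz, sc.z1, 1, best);
  if (sc.glass_t > 0.0) plane_hit(z, dz, sc.z2, 2, best);
  plane_hit(z, dz, sc.height, 4, best);
  if (sc.barrier_on) {
    plane_hit(z, dz, sc.barrier_top, 3, best);
    if (dx != 0.0) {
      double t = (sc.barrier_half - x) / dx;
      if (t > TMIN && t < best.t) {
        double zh = z + t * dz;
        if (zh >= sc.barrier_top && zh <= 0.0) { best.t = t; best.surf = 5; }
      }
      t = (-sc.barrier_half - x) / dx;
      if (t > TMIN && t < best.t) {
        double zh = z + t * dz;
        if (zh >= sc.barrier_top && zh <= 0.0) { best.t = t; best.surf = 6; }
      }
    }
  }
  cyl_hit(sc, x, y, z, dx, dy, dz, best);
  return best;
}

// unpolarized Fresnel reflectance; returns 1 for TIR
static inline double fresnel_R(double n1, double n2, double cosi, double &cost) {
  double eta = n1 / n2;
  double sin2t = eta * eta * (1.0 - cosi * cosi);
  if (sin2t >= 1.0) { cost = 0.0; return 1.0; }
  cost = std::sqrt(1.0 - sin2t);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// --------------------------------------------------- phase functions ----
struct Phase {
  int type;                 // 0 = Henyey-Greenstein, 1 = tabulated inverse CDF
  double g;
  std::vector<double> cosg; // grid, ascending in [-1, 1]
  std::vector<double> cdf;  // matching CDF, 0 -> 1
};

static inline double sample_cos(const Phase &ph, double u) {
  if (ph.type == 0) {
    double g = ph.g;
    if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
    double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    double c = (1.0 + g * g - f * f) / (2.0 * g);
    return std::max(-1.0, std::min(1.0, c));
  }
  // inverse-CDF table lookup with linear interpolation
  const std::vector<double> &cdf = ph.cdf;
  size_t hi = std::upper_bound(cdf.begin(), cdf.end(), u) - cdf.begin();
  if (hi == 0) return ph.cosg.front();
  if (hi >= cdf.size()) return ph.cosg.back();
  size_t lo = hi - 1;
  double dc = cdf[hi] - cdf[lo];
  double f = (dc > 0.0) ? (u - cdf[lo]) / dc : 0.0;
  return ph.cosg[lo] + f * (ph.cosg[hi] - ph.cosg[lo]);
}

static inline void spin(double &ux, double &uy, double &uz,
                        double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = (uz >= 0.0) ? cost : -cost;
  } else {
    double temp = std::sqrt(1.0 - uz * uz);
    double nx = sint * (ux * uz * cosp - uy * sinp) / temp + ux * cost;
    double ny = sint * (uy * uz * cosp + ux * sinp) / temp + uy * cost;
    double nz = -sint * cosp * temp + uz * cost;
    ux = nx; uy = ny; uz = nz;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// ------------------------------------------------------------- launch ----
struct Launch {
  double theta_s;     // radians, signed; positive tilts toward detector (+x)
  double spot_x;      // source spot centre (-d/2)
  double beam_radius; // 0.305 mm on the phantom
  double dxshift;     // chief-ray refraction shift through glass + gap
  double z_entry;     // plane where the beam enters the scene (glass top or 0)
};

static Launch make_launch(const Scene &sc, double theta_s_deg, double spot_x,
                          double beam_radius) {
  Launch L;
  L.theta_s = theta_s_deg * M_PI / 180.0;
  L.spot_x = spot_x;
  L.beam_radius = beam_radius;
  double s = std::sin(L.theta_s);
  if (sc.glass_t > 0.0) {
    // aim so the refracted chief ray lands on the designated spot centre
    double sg = s * sc.n[AMB] / sc.n[GLASS];
    double tg = sg / std::sqrt(1.0 - sg * sg);
    double ta = s / std::sqrt(1.0 - s * s);
    L.dxshift = sc.glass_t * tg + sc.gap_t * ta;
    L.z_entry = sc.z2;
  } else {
    double ta = s / std::sqrt(1.0 - s * s);
    L.dxshift = sc.gap_t * ta;
    L.z_entry = sc.z1; // = 0 when gap_t == 0
  }
  return L;
}

static inline void sample_launch(const Launch &L, Xoshiro &rng,
                                 double &x, double &y, double &z,
                                 double &dx, double &dy, double &dz,
                                 double &fx, double &fy) {
  double cs = std::cos(L.theta_s), sn = std::sin(L.theta_s);
  double rho = std::sqrt(rng.unif()) * L.beam_radius;
  double phi = 2.0 * M_PI * rng.unif();
  fx = L.spot_x + rho * std::cos(phi) / cs; // surface footprint (ellipse)
  fy = rho * std::sin(phi);
  dx = sn; dy = 0.0; dz = cs;
  double ex = fx - L.dxshift; // entry point on z_entry plane
  double back = 0.5 / dz;     // start 0.5 mm above the entry plane
  x = ex - dx * back;
  y = fy;
  z = L.z_entry - 0.5;
}

// ------------------------------------------------------------ detect ----
struct Detect {
  double spot_x;          // +d/2
  double semi_x, semi_y;  // projected spot ellipse semi-axes
  double ax, az;          // acceptance-cone axis (unit, pointing up, dz < 0)
  double cos_alpha;
};

static inline bool accepted(const Detect &D, double exit_x, double exit_y,
                            double dx, double dy, double dz) {
  (void)dy;
  double rx = (exit_x - D.spot_x) / D.semi_x;
  double ry = exit_y / D.semi_y;
  if (rx * rx + ry * ry > 1.0) return false;
  double dot = dx * D.ax + dz * D.az;
  return dot >= D.cos_alpha;
}

// ------------------------------------------------------------ kernel ----
static Scene scene_from_list(const List &sc) {
  Scene s;
  s.gap_t = as<double>(sc["gap_t"]);
  s.glass_t = as<double>(sc["glass_t"]);
  s.z1 = -s.gap_t;
  s.z2 = -(s.gap_t + s.glass_t);
  s.barrier_on = as<bool>(sc["barrier_on"]);
  s.barrier_half = as<double>(sc["barrier_half"]);
  double above = as<double>(sc["barrier_above"]); // extension above glass top
  s.barrier_top = s.z2 - above;
  s.radius = as<double>(sc["radius"]);
  s.height = as<double>(sc["height"]);
  s.R2 = s.radius * s.radius;
  s.n[AMB] = 1.0;
  s.n[PH] = as<double>(sc["n_phantom"]);
  s.n[GLASS] = as<double>(sc["n_glass"]);
  s.n[GAP] = as<double>(sc["n_gap"]);
  s.n[BARRIER] = 1.0;
  s.mua[AMB] = 0.0;
  s.mua[PH] = as<double>(sc["mua_phantom"]);
  s.mua[GLASS] = as<double>(sc["mua_glass"]);
  s.mua[GAP] = 0.0;
  s.mua[BARRIER] = 0.0;
  s.mus_p = as<double>(sc["mus_phantom"]);
  s.mut_p = s.mua[PH] + s.mus_p;
  return s;
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(List scene, List source, List detector, List phase,
                List control) {
  Scene sc = scene_from_list(scene);
  Launch L = make_launch(sc, as<double>(source["theta_s"]),
                         as<double>(source["spot_x"]),
                         as<double>(source["beam_radius"]));
  Detect D;
  D.spot_x = as<double>(detector["spot_x"]);
  D.semi_x = as<double>(detector["semi_x"]);
  D.semi_y = as<double>(detector["semi_y"]);
  D.ax = as<double>(detector["axis_x"]);
  D.az = as<double>(detector["axis_z"]);
  D.cos_alpha = as<double>(detector["cos_alpha"]);

  Phase ph;
  ph.type = as<int>(phase["type"]);
  ph.g = as<double>(phase["g"]);
  if (ph.type == 1) {
    ph.cosg = as<std::vector<double> >(phase["cos_grid"]);
    ph.cdf = as<std::vector<double> >(phase["cdf"]);
  }

  const int n_photons = as<int>(control["n_photons"]);
  const int seed = as<int>(control["seed"]);
  const int stream = as<int>(control["stream"]);
  const double wth = as<double>(control["roulette_threshold"]);
  const double msur = as<double>(control["roulette_m"]);
  const long max_events = (long)as<double>(control["max_events"]);
  const bool rec_density = as<bool>(control["record_density"]);

  // density grid (x, z) over the banana region
  int nx = 0, nz = 0;
  double gx0 = 0, gx1 = 0, gz0 = 0, gz1 = 0, cw = 0, ch = 0;
  NumericMatrix dens(1, 1);
  if (rec_density) {
    NumericVector gs = control["density_grid"]; // x0, x1, z0, z1, nx, nz
    gx0 = gs[0]; gx1 = gs[1]; gz0 = gs[2]; gz1 = gs[3];
    nx = (int)gs[4]; nz = (int)gs[5];
    dens = NumericMatrix(nz, nx);
    cw = (gx1 - gx0) / nx; ch = (gz1 - gz0) / nz;
  }
  std::vector<double> segs; // x0,z0,x1,z1 per in-phantom move
  segs.reserve(rec_density ? 4096 : 0);
  const size_t SEG_CAP = 400000;

  Xoshiro rng(stream_key(seed, stream));

  double detected_w = 0, escaped_w = 0, side_w = 0, deposited_w = 0,
         barrier_w = 0, roulette_killed_w = 0, roulette_boost_w = 0;
  double sum_wl = 0, sum_wdepth = 0;         // over detected photons
  double side_sum_wl = 0;                     // over side/bottom exits
  long n_detected = 0, n_cap = 0, n_side = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x, y, z, dx, dy, dz, fx, fy;
    sample_launch(L, rng, x, y, z, dx, dy, dz, fx, fy);
    double w = 1.0, l = 0.0, maxz = 0.0, tau = 0.0;
    bool has_exit = false;
    double exit_x = 0, exit_y = 0;
    int cur = material_of(sc, x, y, z);
    long events = 0;
    if (rec_density) segs.clear();

    bool alive = true;
    while (alive) {
      if (++events > max_events) { deposited_w += w; ++n_cap; break; }
      if (cur == BARRIER) { barrier_w += w; break; }

      Hit hb;
      double s_move;
      bool to_boundary;
      if (cur == PH) {
        if (sc.mus_p > 0.0) {
          if (tau <= 0.0) tau = -std::log(1.0 - rng.unif());
          double s_free = tau / sc.mut_p;
          // fast path: step cannot reach any phantom surface
          if (s_free < z && s_free < sc.radius && s_free < sc.height - z &&
              x * x + y * y <= (sc.radius - s_free) * (sc.radius - s_free)) {
            to_boundary = false;
            s_move = s_free;
            hb.t = INF_T; hb.surf = -1;
          } else {
            hb = phantom_boundary(sc, x, y, z, dx, dy, dz);
            to_boundary = (s_free >= hb.t);
            s_move = to_boundary ? hb.t : s_free;
          }
        } else {
          hb = phantom_boundary(sc, x, y, z, dx, dy, dz);
          // non-scattering phantom: pure Lambert-Beer over the chord
          to_boundary = true;
          s_move = hb.t;
          if (sc.mua[PH] > 0.0) {
            double w2 = w * std::exp(-sc.mua[PH] * s_move);
            deposited_w += w - w2; w = w2;
          }
        }
        if (rec_density && segs.size() < SEG_CAP) {
          segs.push_back(x); segs.push_back(z);
          segs.push_back(x + dx * s_move); segs.push_back(z + dz * s_move);
        }
        x += dx * s_move; y += dy * s_move; z += dz * s_move;
        l += s_move;
        if (z > maxz) maxz = z;
        if (!to_boundary) {
          tau = 0.0;
          double dw = w * sc.mua[PH] / sc.mut_p;
          deposited_w += dw; w -= dw;
          if (w < wth) {
            if (rng.unif() < 1.0 / msur) { roulette_boost_w += w * (msur - 1.0); w *= msur; }
            else { roulette_killed_w += w; break; }
          }
          double cost = sample_cos(ph, rng.unif());
          double phi = 2.0 * M_PI * rng.unif();
          spin(dx, dy, dz, cost, phi);
          continue;
        }
        tau -= hb.t * sc.mut_p;
        if (tau < 0.0) tau = 0.0;
      } else {
        hb = any_boundary(sc, x, y, z, dx, dy, dz);
        if (hb.surf < 0) {
          // free ray: classify terminal state
          if (has_exit && dz < 0.0 && accepted(D, exit_x, exit_y, dx, dy, dz)) {
            detected_w += w; ++n_detected;
            sum_wl += w * l; sum_wdepth += w * maxz;
            if (rec_density) {
              for (size_t k = 0; k + 3 < segs.size(); k += 4) {
                double sx0 = segs[k], sz0 = segs[k + 1];
                double sx1 = segs[k + 2], sz1 = segs[k + 3];
                double len = std::hypot(sx1 - sx0, sz1 - sz0);
                int nstep = 1 + (int)(len / (0.25 * std::min(cw, ch)));
                double ds = len / nstep;
                for (int q = 0; q < nstep; ++q) {
                  double f = (q + 0.5) / nstep;
                  double px = sx0 + f * (sx1 - sx0);
                  double pz = sz0 + f * (sz1 - sz0);
                  int ix = (int)((px - gx0) / cw);
                  int iz = (int)((pz - gz0) / ch);
                  if (ix >= 0 && ix < nx && iz >= 0 && iz < nz)
                    dens(iz, ix) += w * ds;
                }
              }
            }
          } else if (dz < 0.0 || z < 0.0) {
            escaped_w += w;
          } else {
            side_w += w; side_sum_wl += w * l; ++n_side;
          }
          break;
        }
        // Lambert-Beer attenuation along the chord (glass only)
        if (sc.mua[cur] > 0.0) {
          double w2 = w * std::exp(-sc.mua[cur] * hb.t);
          deposited_w += w - w2; w = w2;
        }
        x += dx * hb.t; y += dy * hb.t; z += dz * hb.t;
      }

      // ---- boundary event at surface hb.surf ----
      int far = material_of(sc, x + dx * 1e-6, y + dy * 1e-6, z + dz * 1e-6);
      if (far == cur) { x += dx * PUSH; y += dy * PUSH; z += dz * PUSH; continue; }
      if (far == BARRIER) { barrier_w += w; break; }
      // side/bottom exits terminate: edge photons cannot reach the detector
      if (far == AMB && (hb.surf == 7 || hb.surf == 4)) {
        side_w += w; side_sum_wl += w * l; ++n_side;
        break;
      }
      double n1 = sc.n[cur], n2 = sc.n[far];
      if (n1 == n2) {
        if (cur == PH && hb.surf == 0 && dz < 0.0) {
          exit_x = x; exit_y = y; has_exit = true;
        }
        cur = far;
        x += dx * PUSH; y += dy * PUSH; z += dz * PUSH;
        continue;
      }
      // surface normal
      double nxn = 0, nyn = 0, nzn = 0;
      if (hb.surf == 5 || hb.surf == 6) { nxn = 1.0; }
      else if (hb.surf == 7) {
        double r = std::sqrt(x * x + y * y);
        nxn = x / r; nyn = y / r;
      } else { nzn = 1.0; }
      double c1 = dx * nxn + dy * nyn + dz * nzn; // signed incidence
      double sgn = (c1 >= 0.0) ? 1.0 : -1.0;
      double cosi = c1 * sgn;
      double cost;
      double R = fresnel_R(n1, n2, cosi, cost);
      if (rng.unif() < R) {
        dx -= 2.0 * c1 * nxn; dy -= 2.0 * c1 * nyn; dz -= 2.0 * c1 * nzn;
      } else {
        double eta = n1 / n2;
        dx = eta * dx + (cost - eta * cosi) * sgn * nxn;
        dy = eta * dy + (cost - eta * cosi) * sgn * nyn;
        dz = eta * dz + (cost - eta * cosi) * sgn * nzn;
        double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
        dx /= nrm; dy /= nrm; dz /= nrm;
        if (cur == PH && hb.surf == 0 && dz < 0.0) {
          exit_x = x; exit_y = y; has_exit = true;
        }
        cur = far;
      }
      x += dx * PUSH; y += dy * PUSH; z += dz * PUSH;
    }
  }

  List out = List::create(
    _["n_photons"] = (double)n_photons,
    _["detected_w"] = detected_w,
    _["n_detected"] = (double)n_detected,
    _["sum_wl"] = sum_wl,
    _["sum_wdepth"] = sum_wdepth,
    _["escaped_w"] = escaped_w,
    _["side_w"] = side_w,
    _["n_side"] = (double)n_side,
    _["side_sum_wl"] = side_sum_wl,
    _["deposited_w"] = deposited_w,
    _["barrier_w"] = barrier_w,
    _["roulette_killed_w"] = roulette_killed_w,
    _["roulette_boost_w"] = roulette_boost_w,
    _["n_cap"] = (double)n_cap);
  if (rec_density) out["density"] = dens;
  return out;
}

// Launch sampler exposed for geometric tests: returns the surface footprint
// sample, the starting position in ambient air, and the beam direction.
// [[Rcpp::export(name = ".mc_launch_cpp")]]
NumericMatrix mc_launch_cpp(List scene, List source, int n, int seed, int stream) {
  Scene sc = scene_from_list(scene);
  Launch L = make_launch(sc, as<double>(source["theta_s"]),
                         as<double>(source["spot_x"]),
                         as<double>(source["beam_radius"]));
  Xoshiro rng(stream_key(seed, stream));
  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create("fx", "fy", "x", "y", "z",
                                          "dx", "dy", "dz");
  for (int i = 0; i < n; ++i) {
    double x, y, z, dx, dy, dz, fx, fy;
    sample_launch(L, rng, x, y, z, dx, dy, dz, fx, fy);
    out(i, 0) = fx; out(i, 1) = fy;
    out(i, 2) = x; out(i, 3) = y; out(i, 4) = z;
    out(i, 5) = dx; out(i, 6) = dy; out(i, 7) = dz;
  }
  return out;
}

// Vectorized material lookup used by material_at()
// [[Rcpp::export(name = ".material_at_cpp")]]
IntegerVector material_at_cpp(List scene, NumericVector x, NumericVector y,
                              NumericVector z) {
  Scene sc = scene_from_list(scene);
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = material_of(sc, x[i], y[i], z[i]);
  return out;
}

// Henyey-Greenstein inverse-CDF sampler (vectorized; shared with the kernel)
// [[Rcpp::export(name = ".sample_hg_cpp")]]
NumericVector sample_hg_cpp(double g, NumericVector u) {
  Phase ph; ph.type = 0; ph.g = g;
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_cos(ph, u[i]);
  return out;
}

// Tabulated inverse-CDF sampler (vectorized; shared with the kernel)
// [[Rcpp::export(name = ".sample_table_cpp")]]
NumericVector sample_table_cpp(NumericVector cos_grid, NumericVector cdf,
                               NumericVector u) {
  Phase ph; ph.type = 1; ph.g = 0;
  ph.cosg = as<std::vector<double> >(cos_grid);
  ph.cdf = as<std::vector<double> >(cdf);
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_cos(ph, u[i]);
  return out;
}
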