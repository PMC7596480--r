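#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Geometry in SI meters. mode 0 = straight channel (one cylinder of length
// xab), mode 1 = two tubes joined by a cubic cavity. Axis x runs from the
// ipsilateral source plane (x = 0, reflecting) to the contralateral absorbing
// plane (x = xab).
struct Geom {
  int mode;
  double R, R2;          // tube radius, radius^2
  double xin, xout, xab; // tube/cavity interfaces and absorbing plane
  double h;              // cavity half side
};

static Geom as_geom(const NumericVector& g) {
  Geom gm;
  gm.mode = (int)g[0];
  gm.R = g[1]; gm.R2 = g[1] * g[1];
  gm.xin = g[2]; gm.xout = g[3]; gm.xab = g[4];
  gm.h = g[5];
  return gm;
}

// region codes: 0 ipsi tube, 1 cavity, 2 contra tube, 3 outside.
// Half-open axial convention [x_lo, x_hi); the absorbing end x == xab is
// kept in the contralateral region (the domain is closed there).
static int region_of(const Geom& g, double x, double y, double z) {
  double r2 = y * y + z * z;
  if (x < 0.0 || x > g.xab) return 3;
  if (g.mode == 0) {
    if (r2 > g.R2) return 3;
    if (x < g.xin) return 0;
    if (x < g.xout) return 1;
    return 2;
  }
  if (x < g.xin) return (r2 <= g.R2) ? 0 : 3;
  if (x < g.xout)
    return (std::fabs(y) <= g.h && std::fabs(z) <= g.h) ? 1 : 3;
  return (r2 <= g.R2) ? 2 : 3;
}

static const double TEPS = 1e-13; // parametric tolerance along a segment
static const double NUDGE = 1e-12; // metres; pushes points off surfaces

// earliest crossing of plane x_k = c along p + t*d, t in (TEPS, 1]
static inline double plane_t(double p, double d, double c) {
  if (d == 0.0) return 2.0;
  double t = (c - p) / d;
  return (t > TEPS && t <= 1.0) ? t : 2.0;
}

// earliest exit through the cylinder y^2 + z^2 = R^2
static inline double cyl_t(const Geom& g, const double* p, const double* d) {
  double A = d[1] * d[1] + d[2] * d[2];
  if (A == 0.0) return 2.0;
  double B = p[1] * d[1] + p[2] * d[2];
  double C = p[1] * p[1] + p[2] * p[2] - g.R2;
  double disc = B * B - A * C;
  if (disc < 0.0) return 2.0;
  double t = (-B + std::sqrt(disc)) / A; // outward root (inside => C <= 0)
  return (t > TEPS && t <= 1.0) ? t : 2.0;
}

// Advance a particle from a (inside the domain) toward proposed endpoint b,
// applying specular reflection at walls, walking through region interfaces,
// and detecting absorption at x = xab. Returns 0 ok (a updated to the
// corrected endpoint), 1 absorbed (a holds the crossing point on the plane),
// 2 rejected (a left unchanged; caller should keep the old position).
static int advance(const Geom& g, double* a, const double* b_in,
                   int max_ref, int* nref) {
  double cur[3] = {a[0], a[1], a[2]};
  double b[3] = {b_in[0], b_in[1], b_in[2]};
  *nref = 0;
  for (int guard = 0; guard < 64; ++guard) {
    int reg = region_of(g, cur[0], cur[1], cur[2]);
    if (reg == 3) return 2;
    double d[3] = {b[0] - cur[0], b[1] - cur[1], b[2] - cur[2]};

    // candidate surfaces for the current region
    // surf: 0 plane x=0 (wall), 1 cylinder (wall), 2 plane xin, 3 plane xout,
    //       4..7 cavity faces y=+h,y=-h,z=+h,z=-h (walls), 8 plane xab
    double tbest = 2.0; int surf = -1;
    auto consider = [&](double t, int s) { if (t < tbest) { tbest = t; surf = s; } };
    bool tube_like = (g.mode == 0) || reg == 0 || reg == 2;
    if (tube_like) consider(cyl_t(g, cur, d), 1);
    if (g.mode == 0) {
      consider(plane_t(cur[0], d[0], 0.0), 0);
      consider(plane_t(cur[0], d[0], g.xab), 8);
    } else if (reg == 0) {
      consider(plane_t(cur[0], d[0], 0.0), 0);
      consider(plane_t(cur[0], d[0], g.xin), 2);
    } else if (reg == 1) {
      consider(plane_t(cur[0], d[0], g.xin), 2);
      consider(plane_t(cur[0], d[0], g.xout), 3);
      consider(plane_t(cur[1], d[1], g.h), 4);
      consider(plane_t(cur[1], d[1], -g.h), 5);
      consider(plane_t(cur[2], d[2], g.h), 6);
      consider(plane_t(cur[2], d[2], -g.h), 7);
    } else { // contra tube
      consider(plane_t(cur[0], d[0], g.xout), 3);
      consider(plane_t(cur[0], d[0], g.xab), 8);
    }

    if (tbest > 1.0) { // no crossing: accept endpoint if numerically inside
      if (region_of(g, b[0], b[1], b[2]) == 3) return 2;
      a[0] = b[0]; a[1] = b[1]; a[2] = b[2];
      return 0;
    }

    double hit[3] = {cur[0] + tbest * d[0], cur[1] + tbest * d[1],
                     cur[2] + tbest * d[2]};

    if (surf == 8) { // absorbing plane
      a[0] = g.xab; a[1] = hit[1]; a[2] = hit[2];
      return 1;
    }

    // interface planes between tube and cavity: crossing through the tube
    // disk continues into the next region; through the annulus it is a wall
    bool is_wall = true;
    if (g.mode == 1 && (surf == 2 || surf == 3)) {
      double r2 = hit[1] * hit[1] + hit[2] * hit[2];
      if (r2 <= g.R2) { // continue through the mouth disk
        cur[0] = hit[0] + (d[0] > 0 ? NUDGE : -NUDGE);
        cur[1] = hit[1]; cur[2] = hit[2];
        is_wall = false;
      }
    }
    if (!is_wall) continue;

    // outward unit normal at the hit point
    double n[3] = {0.0, 0.0, 0.0};
    switch (surf) {
      case 0: n[0] = -1.0; break;
      case 1: { double r = std::sqrt(hit[1] * hit[1] + hit[2] * hit[2]);
                if (r == 0.0) return 2;
                n[1] = hit[1] / r; n[2] = hit[2] / r; } break;
      case 2: n[0] = -1.0; break; // cavity annulus face at xin (hit moving -x)
      case 3: n[0] = 1.0; break;  // cavity annulus face at xout
      case 4: n[1] = 1.0; break;
      case 5: n[1] = -1.0; break;
      case 6: n[2] = 1.0; break;
      case 7: n[2] = -1.0; break;
      default: return 2;
    }
    if (++(*nref) > max_ref) return 2;
    // mirror the remaining displacement across the tangent plane at the hit
    double rem[3] = {b[0] - hit[0], b[1] - hit[1], b[2] - hit[2]};
    double dot = rem[0] * n[0] + rem[1] * n[1] + rem[2] * n[2];
    b[0] = hit[0] + rem[0] - 2.0 * dot * n[0];
    b[1] = hit[1] + rem[1] - 2.0 * dot * n[1];
    b[2] = hit[2] + rem[2] - 2.0 * dot * n[2];
    cur[0] = hit[0] - NUDGE * n[0];
    cur[1] = hit[1] - NUDGE * n[1];
    cur[2] = hit[2] - NUDGE * n[2];
  }
  return 2;
}

// [[Rcpp::export]]
List cpp_advance_segment(NumericVector from, NumericVector to,
                         NumericVector geom, int max_ref) {
  Geom g = as_geom(geom);
  double a[3] = {from[0], from[1], from[2]};
  double a0[3] = {a[0], a[1], a[2]};
  double b[3] = {to[0], to[1], to[2]};
  int nref = 0;
  int code = advance(g, a, b, max_ref, &nref);
  if (code == 2) { a[0] = a0[0]; a[1] = a0[1]; a[2] = a0[2]; }
  return List::create(_["endpoint"] = NumericVector::create(a[0], a[1], a[2]),
                      _["n_reflections"] = nref,
                      _["status"] = code); // 0 ok, 1 absorbed, 2 rejected
}

// [[Rcpp::export]]
IntegerVector cpp_region_of(NumericMatrix pts, NumericVector geom) {
  Geom g = as_geom(geom);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = region_of(g, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Fast internal RNG: xoshiro256++ with polar-method Gaussians. Seeded from
// R's RNG stream at kernel entry, so results remain a deterministic
// function of set.seed() while avoiding the cost of R's inversion sampler
// in the hot loop.
struct FastRng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed_from_R() {
    uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t v = (hi << 32) ^ lo;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(v);
    have_spare = false;
    zig_init();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline uint32_t rand32() { return (uint32_t)(next() >> 32); }

  // Marsaglia-Tsang ziggurat tables for the standard normal
  static uint32_t zkn[128];
  static double zwn[128], zfn[128];
  static bool ztab_ready;
  static void zig_init() {
    if (ztab_ready) return;
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    zkn[0] = (uint32_t)((dn / q) * m1); zkn[1] = 0;
    zwn[0] = q / m1; zwn[127] = dn / m1;
    zfn[0] = 1.0; zfn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      zkn[i + 1] = (uint32_t)((dn / tn) * m1); tn = dn;
      zfn[i] = std::exp(-0.5 * dn * dn); zwn[i] = dn / m1;
    }
    ztab_ready = true;
  }
  inline double norm() {
    for (;;) {
      int32_t hz = (int32_t)rand32();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (az < zkn[iz]) return hz * zwn[iz];
      const double r = 3.442620;
      double x = hz * zwn[iz];
      if (iz == 0) { // tail
        double y;
        do {
          x = -std::log(unif()) * 0.2904764; // 1/r
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      if (zfn[iz] + unif() * (zfn[iz - 1] - zfn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};
uint32_t FastRng::zkn[128];
double FastRng::zwn[128];
double FastRng::zfn[128];
bool FastRng::ztab_ready = false;

// pairwise softened Coulomb forces among active particles; fills f (N x 3)
static void pair_forces(const std::vector<double>& px,
                        const std::vector<double>& py,
                        const std::vector<double>& pz,
                        const std::vector<int>& alive,
                        double kqq, double cut2, double s2,
                        std::vector<double>& fx, std::vector<double>& fy,
                        std::vector<double>& fz) {
  size_t n = px.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  if (kqq == 0.0) return;
  for (size_t i = 0; i + 1 < n; ++i) {
    if (!alive[i]) continue;
    for (size_t j = i + 1; j < n; ++j) {
      if (!alive[j]) continue;
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > cut2) continue;
      double w = kqq / std::pow(d2 + s2, 1.5);
      fx[i] += w * dx; fy[i] += w * dy; fz[i] += w * dz;
      fx[j] -= w * dx; fy[j] -= w * dy; fz[j] -= w * dz;
    }
  }
}

// Euler-Maruyama Brownian dynamics over a sequence of record intervals,
// with synchronous time steps (required when pair forces couple the
// particles). Pair forces may be reused for up to force_refresh seconds
// (multiple time stepping); 0 recomputes every step. Seeded from R's RNG
// (set.seed() before the call). Returns cumulative absorbed counts at the
// end of each interval plus the final ensemble.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, LogicalVector active0,
                  NumericVector abs_time0, NumericVector geom,
                  double D, double mu, double f_ext_x,
                  double kqq, double cutoff, double softening,
                  NumericVector rec_dur, double t_start,
                  double dt_user, double dt_diff, double step_cap,
                  int max_ref, bool walls, bool snapshots,
                  double force_refresh) {
  Geom g = as_geom(geom);
  int n = pos0.nrow();
  std::vector<double> px(n), py(n), pz(n);
  std::vector<int> alive(n);
  std::vector<double> at(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1); pz[i] = pos0(i, 2);
    alive[i] = active0[i] ? 1 : 0;
    at[i] = abs_time0[i];
  }
  std::vector<double> fx(n), fy(n), fz(n);
  bool inter = kqq != 0.0;
  double cut2 = cutoff * cutoff, s2 = softening * softening;

  int n_rec = rec_dur.size();
  IntegerVector counts(n_rec);
  double t = t_start;
  long long n_moves = 0, n_reject = 0;
  double dt_min = R_PosInf, dt_max = 0.0;
  List snaps(snapshots ? n_rec : 0);
  FastRng rng;
  rng.seed_from_R();

  for (int rec = 0; rec < n_rec; ++rec) {
    double span = rec_dur[rec];
    // time step for this interval: user-fixed, else the diffusion rule
    // plus a drift rule for the (uniform) external force; stiff pairwise
    // forces are handled per particle by the trust-region clip below
    double dt = dt_user;
    if (!(dt_user > 0.0)) {
      dt = dt_diff;
      double vext = std::fabs(mu * f_ext_x);
      if (vext > 0.0) dt = std::min(dt, step_cap / vext);
    }
    if (!(dt > 0.0)) stop("non-positive time step");
    int n_sub = (int)std::ceil(span / dt - 1e-9);
    if (n_sub < 1) n_sub = 1;
    dt = span / n_sub;
    if (dt < dt_min) dt_min = dt;
    if (dt > dt_max) dt_max = dt;
    double sig = std::sqrt(2.0 * D * dt);

    int refresh_every = 1;
    if (inter && force_refresh > 0.0) {
      refresh_every = (int)std::floor(force_refresh / dt);
      if (refresh_every < 1) refresh_every = 1;
    }
    for (int s = 0; s < n_sub; ++s) {
      if (inter && (s % refresh_every == 0))
        pair_forces(px, py, pz, alive, kqq, cut2, s2, fx, fy, fz);
      for (int i = 0; i < n; ++i) {
        if (!alive[i]) continue;
        double Fx = f_ext_x + (inter ? fx[i] : 0.0);
        double Fy = inter ? fy[i] : 0.0;
        double Fz = inter ? fz[i] : 0.0;
        // trust-region clip: the deterministic drift displacement never
        // exceeds the step cap, which tames the stiff close-pair forces of
        // the softened Coulomb kernel without collapsing the global dt
        double ddx = mu * Fx * dt, ddy = mu * Fy * dt, ddz = mu * Fz * dt;
        double dm2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (dm2 > step_cap * step_cap) {
          double sc = step_cap / std::sqrt(dm2);
          ddx *= sc; ddy *= sc; ddz *= sc;
        }
        double b[3] = {px[i] + ddx + sig * rng.norm(),
                       py[i] + ddy + sig * rng.norm(),
                       pz[i] + ddz + sig * rng.norm()};
        ++n_moves;
        if (!walls) { px[i] = b[0]; py[i] = b[1]; pz[i] = b[2]; continue; }
        double a[3] = {px[i], py[i], pz[i]};
        int nref = 0;
        int code = advance(g, a, b, max_ref, &nref);
        if (code == 2) { ++n_reject; continue; } // resample next step
        px[i] = a[0]; py[i] = a[1]; pz[i] = a[2];
        if (code == 1) { alive[i] = 0; at[i] = t + (s + 1.0) * dt; }
      }
      if ((s & 1023) == 0) checkUserInterrupt();
    }
    t += span;
    int nabs = 0;
    for (int i = 0; i < n; ++i) if (!alive[i]) ++nabs;
    counts[rec] = nabs;
    if (snapshots) {
      NumericMatrix snap(n, 3);
      for (int i = 0; i < n; ++i) {
        snap(i, 0) = px[i]; snap(i, 1) = py[i]; snap(i, 2) = pz[i];
      }
      snaps[rec] = snap;
    }
  }

  NumericMatrix pos(n, 3);
  LogicalVector act(n);
  NumericVector abt(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = px[i]; pos(i, 1) = py[i]; pos(i, 2) = pz[i];
    act[i] = alive[i] == 1;
    abt[i] = at[i];
  }
  List out = List::create(
      _["positions"] = pos, _["active"] = act, _["absorption_time"] = abt,
      _["counts"] = counts, _["time"] = t,
      _["n_moves"] = (double)n_moves, _["n_reject"] = (double)n_reject,
      _["dt_min"] = dt_min, _["dt_max"] = dt_max);
  if (snapshots) out["snapshots"] = snaps;
  return out;
}

// Per-particle adaptive-step kernel for NON-interacting ensembles.
// Particles are independent, so each is advanced on its own clock. The
// per-axis noise scale is tied to the local geometric feature that must be
// resolved: sigma <= S/5 with S = tube_radius inside the tubes and, in the
// cavity interior, S = max(tube_radius, distance to the nearer tube-mouth
// face) — cavity side walls are flat planes, for which specular reflection
// of the proposed segment is exact at any step size, while the 50 um mouth
// disks must be approached with fine steps so the escape flux is resolved.
// A particle more than k*sigma from a face has a ~1e-7 chance per step of
// reaching it, so coarse interior steps do not bias mouth passage. The
// deterministic drift displacement is capped by the same local scale.
// Absorption times are exact step-end times; the arrival curve is binned
// from them afterwards.
// [[Rcpp::export]]
List cpp_simulate_adaptive(NumericMatrix pos0, LogicalVector active0,
                           NumericVector abs_time0, NumericVector geom,
                           double D, double mu, double f_ext_x,
                           double t_start, double t_end, int max_ref) {
  Geom g = as_geom(geom);
  int n = pos0.nrow();
  FastRng rng;
  rng.seed_from_R();
  NumericMatrix pos = clone(pos0);
  LogicalVector act = clone(active0);
  NumericVector abt = clone(abs_time0);
  long long n_moves = 0, n_reject = 0;
  double dt_min = R_PosInf, dt_max = 0.0;
  double base_cap = g.R / 5.0;
  double v_ext = mu * f_ext_x;
  bool has_drift = v_ext != 0.0;
  if (D <= 0.0 && !has_drift)
    stop("adaptive kernel needs D > 0 or a nonzero force");

  for (int i = 0; i < n; ++i) {
    if (!act[i]) continue;
    double a[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double t = t_start;
    while (t < t_end) {
      double scale = base_cap;
      if (g.mode == 1 && a[0] >= g.xin && a[0] < g.xout) {
        // delicate features seen from the cavity are the two tube-mouth
        // disks; everything nearer than that is a flat wall, where
        // specular reflection is exact at any step size
        double dface = std::min(a[0] - g.xin, g.xout - a[0]);
        double rxy = std::sqrt(a[1] * a[1] + a[2] * a[2]);
        double lat = rxy > g.R ? rxy - g.R : 0.0;
        double dfeat = std::sqrt(dface * dface + lat * lat);
        if (dfeat / 5.0 > scale) scale = dfeat / 5.0;
      }
      double dt = t_end - t;
      if (D > 0.0) dt = std::min(dt, scale * scale / (2.0 * D));
      if (has_drift) dt = std::min(dt, scale / std::fabs(v_ext));
      if (dt < dt_min) dt_min = dt;
      if (dt > dt_max) dt_max = dt;
      double sig = std::sqrt(2.0 * D * dt);
      double b[3] = {a[0] + v_ext * dt + sig * rng.norm(),
                     a[1] + sig * rng.norm(),
                     a[2] + sig * rng.norm()};
      ++n_moves;
      int nref = 0;
      double keep[3] = {a[0], a[1], a[2]};
      int code = advance(g, a, b, max_ref, &nref);
      if (code == 2) {
        ++n_reject;
        a[0] = keep[0]; a[1] = keep[1]; a[2] = keep[2];
        t += dt;
        continue;
      }
      t += dt;
      if (code == 1) { act[i] = false; abt[i] = t; break; }
      if ((n_moves & 65535) == 0) checkUserInterrupt();
    }
    pos(i, 0) = a[0]; pos(i, 1) = a[1]; pos(i, 2) = a[2];
  }
  return List::create(_["positions"] = pos, _["active"] = act,
                      _["absorption_time"] = abt, _["time"] = t_end,
                      _["n_moves"] = (double)n_moves,
                      _["n_reject"] = (double)n_reject,
                      _["dt_min"] = dt_min, _["dt_max"] = dt_max);
}

// One precomputed Thomas factorisation of the constant tridiagonal LHS
// (I - theta dt A); solve() overwrites rhs with the solution.
struct TriLU {
  std::vector<double> La, beta, cp;
  int n;
  void init(const NumericVector& lo, const NumericVector& di,
            const NumericVector& up, double theta_dt) {
    n = di.size();
    La.assign(n, 0.0); beta.assign(n, 0.0); cp.assign(n, 0.0);
    std::vector<double> Lb(n), Lc(n);
    for (int i = 0; i < n; ++i) {
      La[i] = (i > 0) ? -theta_dt * lo[i] : 0.0;
      Lb[i] = 1.0 - theta_dt * di[i];
      Lc[i] = (i < n - 1) ? -theta_dt * up[i] : 0.0;
    }
    beta[0] = Lb[0];
    cp[0] = Lc[0] / beta[0];
    for (int i = 1; i < n; ++i) {
      beta[i] = Lb[i] - La[i] * cp[i - 1];
      if (i < n - 1) cp[i] = Lc[i] / beta[i];
    }
  }
  void solve(std::vector<double>& d) const {
    d[0] /= beta[0];
    for (int i = 1; i < n; ++i) d[i] = (d[i] - La[i] * d[i - 1]) / beta[i];
    for (int i = n - 2; i >= 0; --i) d[i] -= cp[i] * d[i + 1];
  }
};

// Crank-Nicolson time stepping of dp/dt = A p with A tridiagonal
// (bands lo, di, up), with n_startup initial backward-Euler steps
// (Rannacher smoothing: plain CN rings on sharp initial data such as a
// point source). Returns the absorbed fraction 1 - sum(p)*dx at the end
// of each block of n_sub steps.
// [[Rcpp::export]]
NumericVector cpp_cn_evolve(NumericVector lo, NumericVector di,
                            NumericVector up, NumericVector p0,
                            double dt, double dx,
                            IntegerVector n_sub_per_rec, int n_startup) {
  int n = p0.size();
  std::vector<double> p(p0.begin(), p0.end());
  TriLU cn, be;
  cn.init(lo, di, up, 0.5 * dt);
  be.init(lo, di, up, dt);
  std::vector<double> rhs(n);
  int n_rec = n_sub_per_rec.size();
  NumericVector out(n_rec);
  long long step = 0;
  for (int rec = 0; rec < n_rec; ++rec) {
    for (int s = 0; s < n_sub_per_rec[rec]; ++s, ++step) {
      if (step < n_startup) {
        rhs = p;          // backward Euler: (I - dt A) p' = p
        be.solve(rhs);
      } else {
        for (int i = 0; i < n; ++i) { // RHS = (I + dt/2 A) p
          double v = (1.0 + 0.5 * dt * di[i]) * p[i];
          if (i > 0) v += 0.5 * dt * lo[i] * p[i - 1];
          if (i < n - 1) v += 0.5 * dt * up[i] * p[i + 1];
          rhs[i] = v;
        }
        cn.solve(rhs);
      }
      p = rhs;
    }
    double mass = 0.0;
    for (int i = 0; i < n; ++i) mass += p[i];
    out[rec] = 1.0 - mass * dx;
  }
  return out;
}
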