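// Core engine: rigid spherocylinder geometry, four-state motor kinetics,
// constraint-based implicit timestep (collision complementarity + tether
// springs in one convex QP solved by BBPGD), and the full run loop.
//
// Units repo-wide: length um, force pN, time s, energy pN*um.
// Arc coordinate s in [-L/2, +L/2], minus end at s = -L/2.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <array>
#include <functional>
#include <unordered_map>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------- small math

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double a) const { return Vec3(x * a, y * a, z * a); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

struct Quat {
  double w, x, y, z;
  Quat() : w(1), x(0), y(0), z(0) {}
  Quat(double a, double b, double c, double d) : w(a), x(b), y(c), z(d) {}
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
  // director: rotate reference axis (0,0,1)
  Vec3 director() const {
    return Vec3(2.0 * (x * z + w * y), 2.0 * (y * z - w * x),
                1.0 - 2.0 * (x * x + y * y));
  }
};

static inline Quat qmul(const Quat& a, const Quat& b) {
  return Quat(a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
              a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
              a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
              a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w);
}

// quaternion exponential map for rotation vector phi
static inline Quat qexp(const Vec3& phi) {
  double th = phi.norm();
  if (th < 1e-12) return Quat(1.0, 0.5 * phi.x, 0.5 * phi.y, 0.5 * phi.z);
  double s = std::sin(0.5 * th) / th;
  return Quat(std::cos(0.5 * th), s * phi.x, s * phi.y, s * phi.z);
}

// deterministic orthonormal frame perpendicular to unit p
static inline void perp_frame(const Vec3& p, Vec3& e1, Vec3& e2) {
  Vec3 a = (std::fabs(p.x) < 0.9) ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
  e1 = p.cross(a);
  double n = e1.norm();
  e1 = e1 * (1.0 / n);
  e2 = p.cross(e1);
}

// --------------------------------------------------------------- counter RNG
// Counter-based generator (splitmix64 finalizer chain). Streams are keyed by
// (seed, step, channel, entity, draw) so trajectories are bit-reproducible
// regardless of how the step loop is chunked between R and C++.

static inline uint64_t sm_mix(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double rng_u01(uint64_t seed, uint64_t step, uint64_t channel,
                             uint64_t entity, uint64_t draw) {
  uint64_t h = sm_mix(seed);
  h = sm_mix(h ^ sm_mix(step + 0x632be59bd9b4e019ULL));
  h = sm_mix(h ^ sm_mix(channel + 0x9e6c63d0876a9f77ULL));
  h = sm_mix(h ^ sm_mix(entity + 0xd6e8feb86659fd93ULL));
  h = sm_mix(h ^ sm_mix(draw));
  // (0,1): top 53 bits, offset by half ulp
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double rng_norm(uint64_t seed, uint64_t step, uint64_t channel,
                              uint64_t entity, uint64_t draw) {
  // Box-Muller using draws (2*draw, 2*draw+1)
  double u1 = rng_u01(seed, step, channel, entity, 2 * draw);
  double u2 = rng_u01(seed, step, channel, entity, 2 * draw + 1);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// ------------------------------------------------------------------ boundary

// kind: 0 free, 1 periodic box, 2 cylinder along x (periodic in x),
//       3 sphere, 4 spherical shell
struct Boundary {
  int kind;
  double bx, by, bz;   // box lengths
  double R;            // cylinder or sphere radius
  double rin, rout;    // shell radii
};

static Boundary parse_boundary(const NumericVector& b) {
  Boundary bd;
  bd.kind = (int)b[0];
  bd.bx = bd.by = bd.bz = 0.0;
  bd.R = bd.rin = bd.rout = 0.0;
  if (bd.kind == 1) { bd.bx = b[1]; bd.by = b[2]; bd.bz = b[3]; }
  else if (bd.kind == 2) { bd.bx = b[1]; bd.R = b[2]; }
  else if (bd.kind == 3) { bd.R = b[1]; }
  else if (bd.kind == 4) { bd.rin = b[1]; bd.rout = b[2]; }
  return bd;
}

static inline double wrap1(double x, double Lb, int& im) {
  double y = x;
  while (y < -0.5 * Lb) { y += Lb; im -= 1; }
  while (y >= 0.5 * Lb) { y -= Lb; im += 1; }
  return y;
}

static inline Vec3 min_image(Vec3 d, const Boundary& b) {
  if (b.kind == 1) {
    d.x -= b.bx * std::round(d.x / b.bx);
    d.y -= b.by * std::round(d.y / b.by);
    d.z -= b.bz * std::round(d.z / b.bz);
  } else if (b.kind == 2) {
    d.x -= b.bx * std::round(d.x / b.bx);
  }
  return d;
}

// ----------------------------------------------------------------- filaments

struct Fil {
  Vec3 x;
  Quat q;
  double L, D;
  bool mobile;
  Vec3 p;                      // director cache
  double zpar, zperp, zrot;    // drag coefficients
  void refresh(double eta) {
    q.normalize();
    p = q.director();
    double lg = std::log(2.0 * L / D);
    zpar = 2.0 * M_PI * eta * L / lg;
    zperp = 2.0 * zpar;
    zrot = M_PI * eta * L * L * L / (3.0 * lg);
  }
  Vec3 point(double s) const { return x + p * s; }
};

static std::vector<Fil> parse_fils(const NumericMatrix& fm, double eta) {
  int n = fm.nrow();
  std::vector<Fil> fs(n);
  for (int i = 0; i < n; ++i) {
    fs[i].x = Vec3(fm(i, 0), fm(i, 1), fm(i, 2));
    fs[i].q = Quat(fm(i, 3), fm(i, 4), fm(i, 5), fm(i, 6));
    fs[i].L = fm(i, 7);
    fs[i].D = fm(i, 8);
    fs[i].mobile = fm(i, 9) != 0.0;
    if (fs[i].L <= 0.0 || fs[i].D <= 0.0)
      stop("filament %d has non-positive length or diameter", i + 1);
    fs[i].refresh(eta);
  }
  return fs;
}

static NumericMatrix fils_to_matrix(const std::vector<Fil>& fs) {
  NumericMatrix fm(fs.size(), 10);
  for (size_t i = 0; i < fs.size(); ++i) {
    fm(i, 0) = fs[i].x.x; fm(i, 1) = fs[i].x.y; fm(i, 2) = fs[i].x.z;
    fm(i, 3) = fs[i].q.w; fm(i, 4) = fs[i].q.x; fm(i, 5) = fs[i].q.y;
    fm(i, 6) = fs[i].q.z;
    fm(i, 7) = fs[i].L; fm(i, 8) = fs[i].D; fm(i, 9) = fs[i].mobile ? 1.0 : 0.0;
  }
  return fm;
}

// ------------------------------------------------------------- motor species

struct Species {
  double kappa, ell0, vm, fstall, ko_s, ko_d, ka, ke, lambda, rc, eps, dmot;
  int dir_a, dir_b;                 // +1 plus-directed, -1 minus-directed
  bool active_a, active_b;
  bool pause_a, pause_b;            // end behavior: true pause, false detach
  bool perm_a, perm_b;              // permanently bound head (never unbinds)
  bool allow_same;                  // may doubly bind the same filament
  bool bind_mobile_only;            // free heads ignore immobile filaments
};

static std::vector<Species> parse_species(const NumericMatrix& sm) {
  int n = sm.nrow();
  std::vector<Species> sp(n);
  for (int i = 0; i < n; ++i) {
    sp[i].kappa = sm(i, 0);  sp[i].ell0 = sm(i, 1);  sp[i].vm = sm(i, 2);
    sp[i].fstall = sm(i, 3); sp[i].ko_s = sm(i, 4);  sp[i].ko_d = sm(i, 5);
    sp[i].ka = sm(i, 6);     sp[i].ke = sm(i, 7);    sp[i].lambda = sm(i, 8);
    sp[i].rc = sm(i, 9);     sp[i].eps = sm(i, 10);  sp[i].dmot = sm(i, 11);
    sp[i].dir_a = (int)sm(i, 12); sp[i].dir_b = (int)sm(i, 13);
    sp[i].active_a = sm(i, 14) != 0; sp[i].active_b = sm(i, 15) != 0;
    sp[i].pause_a = sm(i, 16) != 0;  sp[i].pause_b = sm(i, 17) != 0;
    sp[i].perm_a = sm(i, 18) != 0;   sp[i].perm_b = sm(i, 19) != 0;
    sp[i].allow_same = sm(i, 20) != 0;
    sp[i].bind_mobile_only = sm.ncol() > 21 && sm(i, 21) != 0;
  }
  return sp;
}

// states: 0 = U, 1 = SA, 2 = SB, 3 = D
struct Motor {
  int sp, st;
  Vec3 x;       // position, meaningful in U
  int fa, fb;   // 0-based filament index, -1 unbound
  double sa, sb;
};

static std::vector<Motor> parse_motors(const NumericMatrix& mm) {
  int n = mm.nrow();
  std::vector<Motor> ms(n);
  for (int i = 0; i < n; ++i) {
    ms[i].sp = (int)mm(i, 0); ms[i].st = (int)mm(i, 1);
    ms[i].x = Vec3(mm(i, 2), mm(i, 3), mm(i, 4));
    ms[i].fa = (int)mm(i, 5); ms[i].sa = mm(i, 6);
    ms[i].fb = (int)mm(i, 7); ms[i].sb = mm(i, 8);
  }
  return ms;
}

static NumericMatrix motors_to_matrix(const std::vector<Motor>& ms) {
  NumericMatrix mm(ms.size(), 9);
  for (size_t i = 0; i < ms.size(); ++i) {
    mm(i, 0) = ms[i].sp; mm(i, 1) = ms[i].st;
    mm(i, 2) = ms[i].x.x; mm(i, 3) = ms[i].x.y; mm(i, 4) = ms[i].x.z;
    mm(i, 5) = ms[i].fa; mm(i, 6) = ms[i].sa;
    mm(i, 7) = ms[i].fb; mm(i, 8) = ms[i].sb;
  }
  return mm;
}

// -------------------------------------------------- segment-segment distance

// Closest points of centerline segments. Parallel degeneracy resolved by the
// midpoint of the projected overlap interval (deterministic, symmetric).
static void seg_seg(const Vec3& c1, const Vec3& p1, double h1,
                    const Vec3& c2, const Vec3& p2, double h2,
                    double& s1, double& s2, double& dist, Vec3& nhat) {
  Vec3 r = c1 - c2;
  double b = p1.dot(p2);
  double u = r.dot(p1);
  double v = r.dot(p2);
  double det = 1.0 - b * b;
  double s, t;
  if (det > 1e-12) {
    s = (b * v - u) / det;
    s = std::max(-h1, std::min(h1, s));
    t = v + s * b;
    if (t < -h2 || t > h2) {
      t = std::max(-h2, std::min(h2, t));
      s = std::max(-h1, std::min(h1, t * b - u));
      t = std::max(-h2, std::min(h2, v + s * b));
    }
  } else {
    // parallel: midpoint of the projected overlap interval on segment 1
    double sa = std::max(-h1, std::min(h1, (c2 - p2 * h2 - c1).dot(p1)));
    double sb = std::max(-h1, std::min(h1, (c2 + p2 * h2 - c1).dot(p1)));
    s = 0.5 * (sa + sb);
    t = std::max(-h2, std::min(h2, (c1 + p1 * s - c2).dot(p2)));
  }
  Vec3 pt1 = c1 + p1 * s, pt2 = c2 + p2 * t;
  Vec3 d = pt1 - pt2;
  dist = d.norm();
  if (dist > 1e-13) {
    nhat = d * (1.0 / dist);
  } else {
    Vec3 e1, e2;
    perp_frame(p1, e1, e2);
    nhat = e1;
  }
  s1 = s; s2 = t;
}

// ------------------------------------------------------------------ mobility

struct Wrench { Vec3 f, t; };
struct Twist  { Vec3 v, w; };

static inline Twist mobility_one(const Fil& f, const Wrench& W) {
  Twist U;
  if (!f.mobile) return U;  // immobile: zero mobility block
  double fpar = W.f.dot(f.p);
  Vec3 vpar = f.p * (fpar / f.zpar);
  Vec3 vperp = (W.f - f.p * fpar) * (1.0 / f.zperp);
  U.v = vpar + vperp;
  // axial spin is a null mode: project it out
  Vec3 tperp = W.t - f.p * W.t.dot(f.p);
  U.w = tperp * (1.0 / f.zrot);
  return U;
}

// --------------------------------------------------------------- constraints

struct Con {
  bool bilateral;
  int i, j;        // filament indices, j = -1 for a static wall
  double phi;      // signed gap (uni) or tether length lf (bi)
  double rest;     // 0 or ell0
  double kinv;     // 0 for unilateral and rigid joints, else 1/kappa
  Vec3 n;          // unit, from j's application point toward i's
  Vec3 ri, rj;     // lever arms from filament centers
  Vec3 d;          // min-image vector between application points (j -> i)
  int motor;       // bilateral bookkeeping, else -1
  long key = 0;    // warm-start identity (pair / wall slot / motor id)
};

// pair collision narrow phase (with min image shift of filament j).
// Nearly parallel pairs get a two-point contact manifold (one constraint at
// each end of the projected overlap interval): a single closest-point
// contact lets jammed parallel bundles grind overlap in at the rod ends.
// Appends 0-2 constraints; caller fills i/j indices and keys.
static int pair_contact(const Fil& fi, const Fil& fj, const Boundary& bd,
                        double buffer, Con* out) {
  Vec3 dc = min_image(fj.x - fi.x, bd);
  Vec3 cj = fi.x + dc;  // shifted center of j
  double rad = 0.5 * (fi.D + fj.D);
  // cheap center prefilter
  double reach = 0.5 * fi.L + 0.5 * fj.L + rad + buffer;
  if (dc.dot(dc) > reach * reach) return 0;
  double h1 = 0.5 * fi.L, h2 = 0.5 * fj.L;
  int nout = 0;
  auto emit = [&](double s, double t) {
    Vec3 pti = fi.point(s), ptj = cj + fj.p * t;
    Vec3 d = pti - ptj;
    double dist = d.norm();
    double sep = dist - rad;
    if (sep >= buffer) return;
    Con& c = out[nout];
    c.bilateral = false;
    c.i = -1; c.j = -1;
    c.phi = sep; c.rest = 0.0; c.kinv = 0.0;
    if (dist > 1e-13) {
      c.n = d * (1.0 / dist);
    } else {
      Vec3 e1, e2;
      perp_frame(fi.p, e1, e2);
      c.n = e1;
    }
    c.ri = pti - fi.x;
    c.rj = ptj - cj;
    c.d = d;
    c.motor = -1;
    ++nout;
  };
  double b = fi.p.dot(fj.p);
  if (std::fabs(b) > 0.995) {
    // near-parallel: contacts at both ends of the projected overlap interval
    double sa = std::max(-h1, std::min(h1, (cj - fj.p * h2 - fi.x).dot(fi.p)));
    double sb = std::max(-h1, std::min(h1, (cj + fj.p * h2 - fi.x).dot(fi.p)));
    if (sa > sb) std::swap(sa, sb);
    Vec3 r = fi.x - cj;
    double v = r.dot(fj.p);
    auto t_of = [&](double s) {
      return std::max(-h2, std::min(h2, v + s * b));
    };
    if (sb - sa > 0.5 * rad) {  // distinct points: avoid duplicate rows
      emit(sa, t_of(sa));
      emit(sb, t_of(sb));
    } else {
      emit(0.5 * (sa + sb), t_of(0.5 * (sa + sb)));
    }
  } else {
    double s1, s2, dist;
    Vec3 nhat;
    seg_seg(fi.x, fi.p, h1, cj, fj.p, h2, s1, s2, dist, nhat);
    emit(s1, s2);
  }
  return nout;
}

// wall gaps for one filament; appends constraints (j = -1)
static void wall_contacts(const Fil& f, int idx, const Boundary& bd,
                          double buffer, std::vector<Con>& out) {
  double rad = 0.5 * f.D;
  int slot = 0;
  auto push = [&](double sep, const Vec3& pt, const Vec3& n) {
    ++slot;
    if (sep >= buffer) return;
    Con c;
    c.bilateral = false; c.i = idx; c.j = -1;
    c.phi = sep; c.rest = 0.0; c.kinv = 0.0;
    c.n = n; c.ri = pt - f.x; c.rj = Vec3();
    c.d = Vec3(); c.motor = -1;
    c.key = -((long)idx * 8 + slot);  // wall-contact identity
    out.push_back(c);
  };
  if (bd.kind == 2) {  // cylinder along x, radius R
    for (int e = -1; e <= 1; e += 2) {
      Vec3 pt = f.point(e * 0.5 * f.L);
      double rho = std::sqrt(pt.y * pt.y + pt.z * pt.z);
      if (rho < 1e-9) continue;
      double sep = bd.R - rho - rad;
      Vec3 n(0.0, -pt.y / rho, -pt.z / rho);  // inward
      push(sep, pt, n);
    }
  } else if (bd.kind == 3 || bd.kind == 4) {
    double Rout = (bd.kind == 3) ? bd.R : bd.rout;
    for (int e = -1; e <= 1; e += 2) {
      Vec3 pt = f.point(e * 0.5 * f.L);
      double r = pt.norm();
      if (r < 1e-9) continue;
      double sep = Rout - r - rad;
      push(sep, pt, pt * (-1.0 / r));
    }
    if (bd.kind == 4) {  // inner sphere obstacle: closest point on segment
      double s = std::max(-0.5 * f.L, std::min(0.5 * f.L, -f.x.dot(f.p)));
      Vec3 pt = f.point(s);
      double r = pt.norm();
      if (r > 1e-9) {
        double sep = r - bd.rin - rad;
        push(sep, pt, pt * (1.0 / r));
      }
    }
  }
}

static void collect_collisions_impl(const std::vector<Fil>& fs,
                                    const Boundary& bd, double buffer,
                                    std::vector<Con>& out) {
  int n = fs.size();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (!fs[i].mobile && !fs[j].mobile) continue;
      Con cc[2];
      int nc_ = pair_contact(fs[i], fs[j], bd, buffer, cc);
      for (int m = 0; m < nc_; ++m) {
        cc[m].i = i; cc[m].j = j;
        cc[m].key = 2 * ((long)i * n + j) + m + 1;  // pair/manifold identity
        out.push_back(cc[m]);
      }
    }
  }
  for (int i = 0; i < n; ++i)
    if (fs[i].mobile) wall_contacts(fs[i], i, bd, buffer, out);
}

// tether geometry for a doubly bound motor; returns false when degenerate
static bool tether_geom(const std::vector<Fil>& fs, const Motor& m,
                        const Boundary& bd, double& lf, Vec3& nhat,
                        Vec3& ra_pt, Vec3& rb_pt, Vec3& dvec) {
  const Fil& fa = fs[m.fa];
  const Fil& fb = fs[m.fb];
  ra_pt = fa.point(m.sa);
  rb_pt = fb.point(m.sb);
  dvec = min_image(ra_pt - rb_pt, bd);
  double ptdist = dvec.norm();
  double rad = 0.5 * (fa.D + fb.D);
  lf = std::max(0.0, ptdist - rad);
  if (ptdist > 1e-13) {
    nhat = dvec * (1.0 / ptdist);
    return true;
  }
  nhat = Vec3(1, 0, 0);
  return false;
}

static void collect_tethers_impl(const std::vector<Fil>& fs,
                                 const std::vector<Motor>& ms,
                                 const std::vector<Species>& sp,
                                 const Boundary& bd, std::vector<Con>& out) {
  for (size_t k = 0; k < ms.size(); ++k) {
    const Motor& m = ms[k];
    if (m.st != 3) continue;
    const Species& s = sp[m.sp];
    double lf; Vec3 nhat, ra, rb, dvec;
    tether_geom(fs, m, bd, lf, nhat, ra, rb, dvec);
    Con c;
    c.bilateral = true;
    c.i = m.fa; c.j = m.fb;
    c.phi = lf; c.rest = s.ell0;
    c.kinv = (s.kappa > 0.0) ? 1.0 / s.kappa : 0.0;  // kinv = 0: rigid joint
    c.n = nhat;
    c.ri = ra - fs[m.fa].x;
    // lever arm of j uses the min-imaged application point
    c.rj = (ra - dvec) - fs[m.fb].x;
    c.d = dvec;
    c.motor = (int)k;
    c.key = (long)k;
    out.push_back(c);
  }
}

// ------------------------------------------------------- matrix-free QP step

// forces from constraint magnitudes: F = D gamma
static void apply_D(const std::vector<Con>& cons, const std::vector<double>& g,
                    std::vector<Wrench>& F) {
  for (auto& w : F) { w.f = Vec3(); w.t = Vec3(); }
  for (size_t k = 0; k < cons.size(); ++k) {
    const Con& c = cons[k];
    Vec3 f = c.n * g[k];
    F[c.i].f = F[c.i].f + f;
    F[c.i].t = F[c.i].t + c.ri.cross(f);
    if (c.j >= 0) {
      F[c.j].f = F[c.j].f - f;
      F[c.j].t = F[c.j].t - c.rj.cross(f);
    }
  }
}

// rate of change of gaps: D^T U
static void apply_DT(const std::vector<Con>& cons,
                     const std::vector<Twist>& U, std::vector<double>& out) {
  for (size_t k = 0; k < cons.size(); ++k) {
    const Con& c = cons[k];
    double val = c.n.dot(U[c.i].v + U[c.i].w.cross(c.ri));
    if (c.j >= 0) val -= c.n.dot(U[c.j].v + U[c.j].w.cross(c.rj));
    out[k] = val;
  }
}

static void apply_mobility(const std::vector<Fil>& fs,
                           const std::vector<Wrench>& F,
                           std::vector<Twist>& U) {
  for (size_t i = 0; i < fs.size(); ++i) U[i] = mobility_one(fs[i], F[i]);
}

struct QPWork {
  std::vector<Wrench> F;
  std::vector<Twist> U;
};

// y = M gamma  (M = D^T M D + K^{-1}/h on bilateral diagonal)
static void qp_matvec(const std::vector<Fil>& fs, const std::vector<Con>& cons,
                      double h, const std::vector<double>& g,
                      std::vector<double>& y, QPWork& wk) {
  apply_D(cons, g, wk.F);
  apply_mobility(fs, wk.F, wk.U);
  apply_DT(cons, wk.U, y);
  for (size_t k = 0; k < cons.size(); ++k)
    if (cons[k].bilateral) y[k] += cons[k].kinv / h * g[k];
}

// BBPGD over gamma with gamma_u >= 0 (unilateral entries flagged).
// `scale` (optional, positive) is a Jacobi preconditioner: the iteration
// runs on the diagonally scaled problem, while the stopping rule and the
// reported residual use the original (unscaled) projected gradient.
// `gamma` on entry provides a warm start. Returns iterations used.
static int bbpgd(const std::function<void(const std::vector<double>&,
                                          std::vector<double>&)>& matvec,
                 const std::vector<double>& q, const std::vector<bool>& uni,
                 double tol, int maxit, std::vector<double>& gamma,
                 double& pg_resid, const std::vector<double>* scale = nullptr) {
  size_t n = q.size();
  if (n == 0) { gamma.clear(); pg_resid = 0.0; return 0; }
  std::vector<double> S(n, 1.0);
  if (scale) {
    for (size_t i = 0; i < n; ++i)
      S[i] = ((*scale)[i] > 0.0 && std::isfinite((*scale)[i]))
                 ? 1.0 / std::sqrt((*scale)[i]) : 1.0;
  }
  // scaled variables: gamma = S x, objective gradient gs = S (M S x + q)
  std::vector<double> x(n), qs(n), g(n), mg(n), tmp(n), s(n), y(n), xn(n),
      gn(n);
  if (gamma.size() != n) gamma.assign(n, 0.0);
  for (size_t i = 0; i < n; ++i) {
    x[i] = gamma[i] / S[i];
    qs[i] = S[i] * q[i];
  }
  auto scaled_matvec = [&](const std::vector<double>& v,
                           std::vector<double>& out) {
    for (size_t i = 0; i < n; ++i) tmp[i] = S[i] * v[i];
    matvec(tmp, out);
    for (size_t i = 0; i < n; ++i) out[i] *= S[i];
  };
  // unscaled projected-gradient norm from scaled quantities
  auto pgnorm = [&](const std::vector<double>& xs,
                    const std::vector<double>& gs) {
    double m = 0.0;
    for (size_t i = 0; i < n; ++i) {
      double gam = S[i] * xs[i];
      double grad = gs[i] / S[i];
      double t = gam - grad;
      if (uni[i] && t < 0.0) t = 0.0;
      m = std::max(m, std::fabs(gam - t));
    }
    return m;
  };
  scaled_matvec(x, mg);
  for (size_t i = 0; i < n; ++i) g[i] = mg[i] + qs[i];
  pg_resid = pgnorm(x, g);
  if (pg_resid <= tol) {
    for (size_t i = 0; i < n; ++i) gamma[i] = S[i] * x[i];
    return 0;
  }
  // first step: small fixed step relative to an estimate of ||M||
  scaled_matvec(g, mg);
  double ng = 0.0, nmg = 0.0;
  for (size_t i = 0; i < n; ++i) {
    ng = std::max(ng, std::fabs(g[i]));
    nmg = std::max(nmg, std::fabs(mg[i]));
  }
  double mnorm = (ng > 0.0) ? nmg / ng : 1.0;
  double alpha = 1e-4 / std::max(mnorm, 1e-30);
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    for (size_t i = 0; i < n; ++i) {
      double v = x[i] - alpha * g[i];
      xn[i] = (uni[i] && v < 0.0) ? 0.0 : v;
    }
    scaled_matvec(xn, mg);
    for (size_t i = 0; i < n; ++i) gn[i] = mg[i] + qs[i];
    double sts = 0.0, sty = 0.0, yty = 0.0;
    for (size_t i = 0; i < n; ++i) {
      s[i] = xn[i] - x[i];
      y[i] = gn[i] - g[i];
      sts += s[i] * s[i];
      sty += s[i] * y[i];
      yty += y[i] * y[i];
    }
    x.swap(xn);
    g.swap(gn);
    pg_resid = pgnorm(x, g);
    if (pg_resid <= tol) break;
    // alternate BB1 / BB2 step sizes with positivity safeguard
    double a;
    if (it % 2 == 1) a = (sty > 0.0) ? sts / sty : alpha;
    else a = (yty > 0.0 && sty > 0.0) ? sty / yty : alpha;
    if (!std::isfinite(a) || a <= 0.0) a = alpha;
    alpha = std::min(std::max(a, 1e-14), 1e14);
    if (sts == 0.0) break;  // stalled at a fixed point
  }
  for (size_t i = 0; i < n; ++i) gamma[i] = S[i] * x[i];
  return std::min(it, maxit);
}

// --------------------------------------------------------------- kMC helpers

// centerline arclength of filament inside sphere (x, rc)
static double seg_in_sphere(const Vec3& c, const Vec3& p, double L,
                            const Vec3& x, double rc, double& lo, double& hi) {
  Vec3 d = c - x;
  double bq = p.dot(d);
  double cq = d.dot(d) - rc * rc;
  double disc = bq * bq - cq;
  lo = hi = 0.0;
  if (disc <= 0.0) return 0.0;
  double sq = std::sqrt(disc);
  lo = std::max(-bq - sq, -0.5 * L);
  hi = std::min(-bq + sq, 0.5 * L);
  if (hi <= lo) { lo = hi = 0.0; return 0.0; }
  return hi - lo;
}

struct BindGrid {
  int fil;
  double lo, ds;          // window start and node spacing
  std::vector<double> w;  // unnormalized weights per node (density * ds)
  double total;           // sum(w) = contribution to the rate / (ko_d eps ke)
};

// S->D candidate integral over filament j for a head anchored at point a.
// ell_f(s) = |a - r_j(s)|_minimage - (D_a + D_j)/2, weight exp[-(1-lambda) beta E]
static double s2d_grid(const Vec3& a, const Fil& fj, double rad_sum,
                       const Species& sp, double beta, const Boundary& bd,
                       int nodes, double ecut, BindGrid& grid) {
  grid.total = 0.0;
  grid.w.clear();
  // admissible point-distance band from beta*E <= ecut
  double wband = (sp.kappa > 0.0) ? std::sqrt(2.0 * ecut / (beta * sp.kappa))
                                  : std::numeric_limits<double>::infinity();
  double lo = -0.5 * fj.L, hi = 0.5 * fj.L;
  if (std::isfinite(wband)) {
    double dmax = rad_sum + sp.ell0 + wband;
    Vec3 dc = min_image(fj.x - a, bd);
    // |dc + s p| <= dmax
    double bq = fj.p.dot(dc);
    double cq = dc.dot(dc) - dmax * dmax;
    double disc = bq * bq - cq;
    if (disc <= 0.0) return 0.0;
    double sq = std::sqrt(disc);
    lo = std::max(lo, -bq - sq);
    hi = std::min(hi, -bq + sq);
    if (hi <= lo) return 0.0;
  }
  double ds = (hi - lo) / nodes;
  grid.lo = lo; grid.ds = ds;
  grid.w.resize(nodes);
  Vec3 dc = min_image(fj.x - a, bd);
  double tot = 0.0;
  for (int k = 0; k < nodes; ++k) {
    double s = lo + (k + 0.5) * ds;
    Vec3 r = dc + fj.p * s;
    double lf = std::max(0.0, r.norm() - rad_sum);
    double e = 0.5 * sp.kappa * (lf - sp.ell0) * (lf - sp.ell0);
    double be = beta * e;
    double wk = (be * (1.0 - sp.lambda) > 700.0)
                    ? 0.0
                    : std::exp(-(1.0 - sp.lambda) * be) * ds;
    grid.w[k] = wk;
    tot += wk;
  }
  grid.total = tot;
  return tot;
}

// ----------------------------------------------------------------- main step

struct Diag {
  int nu, nb, iters;
  double pg_resid, comp_resid, bil_resid, min_sep, tol_abs;
};

struct EventLog {
  std::vector<double> step, motor, code, head, fil, s, lf;
  size_t cap;
  bool overflow = false;
  void push(double st, int m, int code_, int head_, int f, double s_,
            double lf_) {
    if (step.size() >= cap) { overflow = true; return; }
    step.push_back(st); motor.push_back(m + 1); code.push_back(code_);
    head.push_back(head_); fil.push_back(f + 1); s.push_back(s_);
    lf.push_back(lf_);
  }
};

// exact diagonal of the QP matrix (Jacobi preconditioner)
static void qp_diag(const std::vector<Fil>& fs, const std::vector<Con>& cons,
                    double h, std::vector<double>& dg) {
  dg.assign(cons.size(), 0.0);
  auto quad = [&](const Fil& f, const Vec3& n, const Vec3& r) {
    if (!f.mobile) return 0.0;
    double fpar = n.dot(f.p);
    double qt = fpar * fpar / f.zpar + (n.dot(n) - fpar * fpar) / f.zperp;
    Vec3 c = r.cross(n);
    Vec3 cperp = c - f.p * c.dot(f.p);
    return qt + cperp.dot(cperp) / f.zrot;
  };
  for (size_t k = 0; k < cons.size(); ++k) {
    const Con& c = cons[k];
    double v = quad(fs[c.i], c.n, c.ri);
    if (c.j >= 0) v += quad(fs[c.j], c.n, c.rj);
    if (c.bilateral) v += c.kinv / h;
    dg[k] = v;
  }
}

// Flat-array (structure-of-arrays) form of the QP operators: the solver's
// per-iteration cost is dominated by streaming these arrays, so they are
// packed contiguously instead of walking the constraint structs.
struct QPOps {
  int nf = 0;
  size_t nc = 0;
  std::vector<int> ci, cj;              // body indices (cj = -1 wall)
  std::vector<double> nv, ti, tj;       // 3*nc: normal, ri x n, rj x n
  std::vector<double> kh;               // kinv / h (0 for unilateral)
  std::vector<double> diag;             // exact QP diagonal
  // per-body mobility data (flat)
  std::vector<double> px, py, pz, izpar, izperp, izrot;
  std::vector<double> F, U;             // 6*nf scratch (f,t) / (v,w)

  void build(const std::vector<Fil>& fs, const std::vector<Con>& cons,
             double h) {
    nf = fs.size();
    nc = cons.size();
    ci.resize(nc); cj.resize(nc);
    nv.resize(3 * nc); ti.resize(3 * nc); tj.resize(3 * nc);
    kh.resize(nc); diag.resize(nc);
    px.resize(nf); py.resize(nf); pz.resize(nf);
    izpar.resize(nf); izperp.resize(nf); izrot.resize(nf);
    F.assign(6 * nf, 0.0); U.assign(6 * nf, 0.0);
    for (int i = 0; i < nf; ++i) {
      px[i] = fs[i].p.x; py[i] = fs[i].p.y; pz[i] = fs[i].p.z;
      double m = fs[i].mobile ? 1.0 : 0.0;
      izpar[i] = m / fs[i].zpar;
      izperp[i] = m / fs[i].zperp;
      izrot[i] = m / fs[i].zrot;
    }
    for (size_t k = 0; k < nc; ++k) {
      const Con& c = cons[k];
      ci[k] = c.i; cj[k] = c.j;
      Vec3 t1 = c.ri.cross(c.n), t2 = c.rj.cross(c.n);
      nv[3 * k] = c.n.x; nv[3 * k + 1] = c.n.y; nv[3 * k + 2] = c.n.z;
      ti[3 * k] = t1.x; ti[3 * k + 1] = t1.y; ti[3 * k + 2] = t1.z;
      tj[3 * k] = t2.x; tj[3 * k + 1] = t2.y; tj[3 * k + 2] = t2.z;
      kh[k] = c.bilateral ? c.kinv / h : 0.0;
    }
    // exact diagonal (Jacobi preconditioner)
    for (size_t k = 0; k < nc; ++k) {
      diag[k] = body_quad(ci[k], &nv[3 * k], &ti[3 * k]) + kh[k];
      if (cj[k] >= 0) diag[k] += body_quad(cj[k], &nv[3 * k], &tj[3 * k]);
    }
  }

  double body_quad(int b, const double* n, const double* t) const {
    double fp = n[0] * px[b] + n[1] * py[b] + n[2] * pz[b];
    double n2 = n[0] * n[0] + n[1] * n[1] + n[2] * n[2];
    double tp = t[0] * px[b] + t[1] * py[b] + t[2] * pz[b];
    double t2 = t[0] * t[0] + t[1] * t[1] + t[2] * t[2];
    return fp * fp * izpar[b] + (n2 - fp * fp) * izperp[b] +
           (t2 - tp * tp) * izrot[b];
  }

  // U(body arrays) = mobility * F
  void mob() {
    for (int b = 0; b < nf; ++b) {
      const double* f = &F[6 * b];
      double fp = f[0] * px[b] + f[1] * py[b] + f[2] * pz[b];
      double cpar = fp * izpar[b];
      U[6 * b] = cpar * px[b] + (f[0] - fp * px[b]) * izperp[b];
      U[6 * b + 1] = cpar * py[b] + (f[1] - fp * py[b]) * izperp[b];
      U[6 * b + 2] = cpar * pz[b] + (f[2] - fp * pz[b]) * izperp[b];
      double tp = f[3] * px[b] + f[4] * py[b] + f[5] * pz[b];
      U[6 * b + 3] = (f[3] - tp * px[b]) * izrot[b];
      U[6 * b + 4] = (f[4] - tp * py[b]) * izrot[b];
      U[6 * b + 5] = (f[5] - tp * pz[b]) * izrot[b];
    }
  }

  // y = M g (+ optional external body force Fext accumulated before mob)
  void matvec(const std::vector<double>& g, std::vector<double>& y) {
    std::fill(F.begin(), F.end(), 0.0);
    for (size_t k = 0; k < nc; ++k) {
      double gv = g[k];
      if (gv == 0.0) continue;
      double* fi = &F[6 * ci[k]];
      const double* n = &nv[3 * k];
      const double* t1 = &ti[3 * k];
      fi[0] += gv * n[0]; fi[1] += gv * n[1]; fi[2] += gv * n[2];
      fi[3] += gv * t1[0]; fi[4] += gv * t1[1]; fi[5] += gv * t1[2];
      if (cj[k] >= 0) {
        double* fj = &F[6 * cj[k]];
        const double* t2 = &tj[3 * k];
        fj[0] -= gv * n[0]; fj[1] -= gv * n[1]; fj[2] -= gv * n[2];
        fj[3] -= gv * t2[0]; fj[4] -= gv * t2[1]; fj[5] -= gv * t2[2];
      }
    }
    mob();
    dtu(y);
    for (size_t k = 0; k < nc; ++k) y[k] += kh[k] * g[k];
  }

  // y = D^T U for the current U scratch
  void dtu(std::vector<double>& y) const {
    for (size_t k = 0; k < nc; ++k) {
      const double* ui = &U[6 * ci[k]];
      const double* n = &nv[3 * k];
      const double* t1 = &ti[3 * k];
      double v = n[0] * ui[0] + n[1] * ui[1] + n[2] * ui[2] +
                 t1[0] * ui[3] + t1[1] * ui[4] + t1[2] * ui[5];
      if (cj[k] >= 0) {
        const double* uj = &U[6 * cj[k]];
        const double* t2 = &tj[3 * k];
        v -= n[0] * uj[0] + n[1] * uj[1] + n[2] * uj[2] +
             t2[0] * uj[3] + t2[1] * uj[4] + t2[2] * uj[5];
      }
      y[k] = v;
    }
  }
};

// Projected Gauss-Seidel sweeps on the flat operators (see pgs_smooth
// rationale below): O(1) local body updates per constraint.
static int pgs_smooth_ops(QPOps& op, const std::vector<double>& q,
                          const std::vector<bool>& uni, double tol,
                          int max_sweeps, std::vector<double>& gamma,
                          double& pg_resid) {
  size_t nc = op.nc;
  std::fill(op.F.begin(), op.F.end(), 0.0);
  for (size_t k = 0; k < nc; ++k) {
    double gv = gamma[k];
    if (gv == 0.0) continue;
    double* fi = &op.F[6 * op.ci[k]];
    const double* n = &op.nv[3 * k];
    const double* t1 = &op.ti[3 * k];
    fi[0] += gv * n[0]; fi[1] += gv * n[1]; fi[2] += gv * n[2];
    fi[3] += gv * t1[0]; fi[4] += gv * t1[1]; fi[5] += gv * t1[2];
    if (op.cj[k] >= 0) {
      double* fj = &op.F[6 * op.cj[k]];
      const double* t2 = &op.tj[3 * k];
      fj[0] -= gv * n[0]; fj[1] -= gv * n[1]; fj[2] -= gv * n[2];
      fj[3] -= gv * t2[0]; fj[4] -= gv * t2[1]; fj[5] -= gv * t2[2];
    }
  }
  op.mob();
  auto mob_one = [&](int b) {
    const double* f = &op.F[6 * b];
    double fp = f[0] * op.px[b] + f[1] * op.py[b] + f[2] * op.pz[b];
    double cpar = fp * op.izpar[b];
    op.U[6 * b] = cpar * op.px[b] + (f[0] - fp * op.px[b]) * op.izperp[b];
    op.U[6 * b + 1] = cpar * op.py[b] + (f[1] - fp * op.py[b]) * op.izperp[b];
    op.U[6 * b + 2] = cpar * op.pz[b] + (f[2] - fp * op.pz[b]) * op.izperp[b];
    double tp = f[3] * op.px[b] + f[4] * op.py[b] + f[5] * op.pz[b];
    op.U[6 * b + 3] = (f[3] - tp * op.px[b]) * op.izrot[b];
    op.U[6 * b + 4] = (f[4] - tp * op.py[b]) * op.izrot[b];
    op.U[6 * b + 5] = (f[5] - tp * op.pz[b]) * op.izrot[b];
  };
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double pg = 0.0;
    for (size_t k = 0; k < nc; ++k) {
      const double* n = &op.nv[3 * k];
      const double* t1 = &op.ti[3 * k];
      const double* ui = &op.U[6 * op.ci[k]];
      double g = n[0] * ui[0] + n[1] * ui[1] + n[2] * ui[2] +
                 t1[0] * ui[3] + t1[1] * ui[4] + t1[2] * ui[5];
      if (op.cj[k] >= 0) {
        const double* uj = &op.U[6 * op.cj[k]];
        const double* t2 = &op.tj[3 * k];
        g -= n[0] * uj[0] + n[1] * uj[1] + n[2] * uj[2] +
             t2[0] * uj[3] + t2[1] * uj[4] + t2[2] * uj[5];
      }
      g += op.kh[k] * gamma[k] + q[k];
      double t = gamma[k] - g;
      if (uni[k] && t < 0.0) t = 0.0;
      pg = std::max(pg, std::fabs(gamma[k] - t));
      if (op.diag[k] <= 0.0) continue;
      double gnew = gamma[k] - g / op.diag[k];
      if (uni[k] && gnew < 0.0) gnew = 0.0;
      double d = gnew - gamma[k];
      if (d == 0.0) continue;
      gamma[k] = gnew;
      double* fi = &op.F[6 * op.ci[k]];
      fi[0] += d * n[0]; fi[1] += d * n[1]; fi[2] += d * n[2];
      fi[3] += d * t1[0]; fi[4] += d * t1[1]; fi[5] += d * t1[2];
      mob_one(op.ci[k]);
      if (op.cj[k] >= 0) {
        double* fj = &op.F[6 * op.cj[k]];
        const double* t2 = &op.tj[3 * k];
        fj[0] -= d * n[0]; fj[1] -= d * n[1]; fj[2] -= d * n[2];
        fj[3] -= d * t2[0]; fj[4] -= d * t2[1]; fj[5] -= d * t2[2];
        mob_one(op.cj[k]);
      }
    }
    pg_resid = pg;
    if (pg <= tol) break;
  }
  return sweep;
}

// Projected Gauss-Seidel sweeps: cheap local smoother run before BBPGD.
// Maintains body wrenches/twists incrementally so one constraint update is
// O(1); excellent at relaxing the local disturbances left by binding /
// unbinding churn between steps, which otherwise cost the global solver
// hundreds of iterations. Returns sweeps used; gamma updated in place.
static int pgs_smooth(const std::vector<Fil>& fs, const std::vector<Con>& cons,
                      double h, const std::vector<double>& q,
                      const std::vector<double>& diag, double tol,
                      int max_sweeps, std::vector<double>& gamma,
                      QPWork& wk, double& pg_resid) {
  size_t nc = cons.size();
  int nf = fs.size();
  wk.F.assign(nf, Wrench());
  wk.U.assign(nf, Twist());
  apply_D(cons, gamma, wk.F);
  apply_mobility(fs, wk.F, wk.U);
  auto grad_k = [&](size_t k) {
    const Con& c = cons[k];
    double val = c.n.dot(wk.U[c.i].v + wk.U[c.i].w.cross(c.ri));
    if (c.j >= 0) val -= c.n.dot(wk.U[c.j].v + wk.U[c.j].w.cross(c.rj));
    if (c.bilateral) val += c.kinv / h * gamma[k];
    return val + q[k];
  };
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double pg = 0.0;
    for (size_t k = 0; k < nc; ++k) {
      const Con& c = cons[k];
      double g = grad_k(k);
      double t = gamma[k] - g;
      if (!c.bilateral && t < 0.0) t = 0.0;
      pg = std::max(pg, std::fabs(gamma[k] - t));
      if (diag[k] <= 0.0) continue;
      double gnew = gamma[k] - g / diag[k];
      if (!c.bilateral && gnew < 0.0) gnew = 0.0;
      double d = gnew - gamma[k];
      if (d == 0.0) continue;
      gamma[k] = gnew;
      Vec3 f = c.n * d;
      wk.F[c.i].f = wk.F[c.i].f + f;
      wk.F[c.i].t = wk.F[c.i].t + c.ri.cross(f);
      wk.U[c.i] = mobility_one(fs[c.i], wk.F[c.i]);
      if (c.j >= 0) {
        wk.F[c.j].f = wk.F[c.j].f - f;
        wk.F[c.j].t = wk.F[c.j].t - c.rj.cross(f);
        wk.U[c.j] = mobility_one(fs[c.j], wk.F[c.j]);
      }
    }
    pg_resid = pg;
    if (pg <= tol) break;
  }
  return sweep;
}

struct Engine {
  std::vector<Fil> fils;
  std::vector<std::array<int, 3>> images;
  std::vector<Motor> motors;
  std::vector<Species> species;
  Boundary bd;
  double eta, h, kbt, buffer, tol_rel, ecut;
  bool brownian;
  int maxit, nodes, pgs_sweeps;
  uint64_t seed;
  long step;
  double time;
  EventLog* ev = nullptr;
  // warm-start caches for the QP (constraint sets persist between steps);
  // two histories allow linear extrapolation of the solution
  struct Warm { double cur, prev; };
  std::unordered_map<long, Warm> warm_uni, warm_bil;
  // S->D integral cache for static-geometry (frozen filament) runs
  bool cache_binding = false;
  struct S2DCache {
    bool valid = false;
    int f = -1;
    double s = 0.0, tot = 0.0;
    std::vector<BindGrid> grids;
  };
  std::vector<S2DCache> s2d_cache;

  // ---- task 1: motor stepping along filaments (co-move is implicit in s)
  void motor_move() {
    for (size_t k = 0; k < motors.size(); ++k) {
      Motor& m = motors[k];
      const Species& sp = species[m.sp];
      if (m.st == 1 || m.st == 2) {
        bool is_a = (m.st == 1);
        bool active = is_a ? sp.active_a : sp.active_b;
        if (!active || sp.vm == 0.0) continue;
        int dir = is_a ? sp.dir_a : sp.dir_b;
        int f = is_a ? m.fa : m.fb;
        double& s = is_a ? m.sa : m.sb;
        s += dir * sp.vm * h;
        end_handle(k, is_a, f, s);
      } else if (m.st == 3) {
        double lf; Vec3 nhat, ra, rb, dvec;
        bool ok = tether_geom(fils, m, bd, lf, nhat, ra, rb, dvec);
        double fmag = sp.kappa * (lf - sp.ell0);
        // force on head A points from a toward b when stretched
        Vec3 f_on_a = ok ? nhat * (-fmag) : Vec3();
        double sa_new = m.sa, sb_new = m.sb;
        if (sp.active_a && sp.vm > 0.0) {
          double fproj = f_on_a.dot(fils[m.fa].p * (double)sp.dir_a);
          double vf = sp.vm *
              std::max(0.0, std::min(1.0, 1.0 + fproj / sp.fstall));
          sa_new += sp.dir_a * vf * h;
        }
        if (sp.active_b && sp.vm > 0.0) {
          Vec3 f_on_b = f_on_a * (-1.0);
          double fproj = f_on_b.dot(fils[m.fb].p * (double)sp.dir_b);
          double vf = sp.vm *
              std::max(0.0, std::min(1.0, 1.0 + fproj / sp.fstall));
          sb_new += sp.dir_b * vf * h;
        }
        m.sa = sa_new; m.sb = sb_new;
        // head A end handling may change state; re-check B only if still bound
        end_handle(k, true, m.fa, m.sa);
        if (m.st == 3 || m.st == 2) end_handle(k, false, m.fb, m.sb);
      }
    }
  }

  void end_handle(size_t k, bool is_a, int f, double& s) {
    Motor& m = motors[k];
    const Species& sp = species[m.sp];
    double half = 0.5 * fils[f].L;
    if (s >= -half && s <= half) return;
    bool pause = is_a ? sp.pause_a : sp.pause_b;
    if (pause) {
      s = std::max(-half, std::min(half, s));
    } else {
      // detach at the end
      if (ev) ev->push(step, (int)k, 5, is_a ? 1 : 2, f,
                       std::max(-half, std::min(half, s)), NA_REAL);
      detach_head(m, is_a);
    }
  }

  void detach_head(Motor& m, bool is_a) {
    if (m.st == 3) {
      m.st = is_a ? 2 : 1;
      if (is_a) { m.fa = -1; m.sa = 0.0; }
      else { m.fb = -1; m.sb = 0.0; }
    } else if ((m.st == 1 && is_a) || (m.st == 2 && !is_a)) {
      int f = is_a ? m.fa : m.fb;
      double s = is_a ? m.sa : m.sb;
      double half = 0.5 * fils[f].L;
      s = std::max(-half, std::min(half, s));
      m.x = wrap_vec(fils[f].point(s));
      m.st = 0; m.fa = m.fb = -1; m.sa = m.sb = 0.0;
    }
  }

  Vec3 wrap_vec(Vec3 v) {
    int dummy = 0;
    if (bd.kind == 1) {
      v.x = wrap1(v.x, bd.bx, dummy);
      v.y = wrap1(v.y, bd.by, dummy);
      v.z = wrap1(v.z, bd.bz, dummy);
    } else if (bd.kind == 2) {
      v.x = wrap1(v.x, bd.bx, dummy);
    }
    return v;
  }

  // reflect an unbound motor at impermeable walls
  Vec3 reflect_walls(Vec3 v) {
    if (bd.kind == 2) {
      double rho = std::sqrt(v.y * v.y + v.z * v.z);
      if (rho > bd.R && rho > 1e-12) {
        double rr = (2.0 * bd.R - rho) / rho;
        if (rr < 0.0) rr = bd.R / rho;  // deep overshoot: place at wall
        v.y *= rr; v.z *= rr;
      }
    } else if (bd.kind == 3 || bd.kind == 4) {
      double R = (bd.kind == 3) ? bd.R : bd.rout;
      double r = v.norm();
      if (r > R && r > 1e-12) {
        double rr = (2.0 * R - r) / r;
        if (rr < 0.0) rr = R / r;
        v = v * rr;
      }
      if (bd.kind == 4) {
        double r2 = v.norm();
        if (r2 < bd.rin && r2 > 1e-12) v = v * ((2.0 * bd.rin - r2) / r2);
      }
    }
    return v;
  }

  // ---- task 2: binding / unbinding kMC (rates at start-of-step geometry)
  void kmc() {
    double beta = 1.0 / kbt;
    int nfil = fils.size();
    for (size_t k = 0; k < motors.size(); ++k) {
      Motor& m = motors[k];
      const Species& sp = species[m.sp];
      uint64_t mid = (uint64_t)k;
      if (m.st == 0) {
        // unbound diffusion
        if (sp.dmot > 0.0) {
          double sd = std::sqrt(2.0 * sp.dmot * h);
          m.x.x += sd * rng_norm(seed, step, 10, mid, 0);
          m.x.y += sd * rng_norm(seed, step, 10, mid, 1);
          m.x.z += sd * rng_norm(seed, step, 10, mid, 2);
          m.x = wrap_vec(reflect_walls(m.x));
        }
        // binding rate (identical for both heads at the same point)
        std::vector<double> lin(nfil, 0.0);
        std::vector<double> los(nfil), his(nfil);
        double linsum = 0.0;
        for (int i = 0; i < nfil; ++i) {
          if (sp.bind_mobile_only && !fils[i].mobile) continue;
          Vec3 dc = min_image(fils[i].x - m.x, bd);
          double rmax = 0.5 * fils[i].L + sp.rc;
          if (dc.dot(dc) > rmax * rmax) continue;
          Vec3 ci = m.x + dc;
          double lo, hi;
          lin[i] = seg_in_sphere(ci, fils[i].p, fils[i].L, m.x, sp.rc, lo, hi);
          los[i] = lo; his[i] = hi;
          linsum += lin[i];
        }
        if (linsum <= 0.0) continue;
        double R = sp.ko_s * 3.0 * sp.eps * sp.ka /
                   (4.0 * M_PI * sp.rc * sp.rc * sp.rc) * linsum;
        double p = 1.0 - std::exp(-R * h);
        bool fa = !sp.perm_a && rng_u01(seed, step, 11, mid, 0) < p;
        bool fb = !sp.perm_b && rng_u01(seed, step, 11, mid, 1) < p;
        if (!fa && !fb) continue;
        bool head_a = fa && fb ? (rng_u01(seed, step, 11, mid, 2) < 0.5) : fa;
        // binding site: filament proportional to captured length, s uniform
        double u = rng_u01(seed, step, 11, mid, 3) * linsum;
        int fi = nfil - 1;
        for (int i = 0; i < nfil; ++i) {
          if (u <= lin[i]) { fi = i; break; }
          u -= lin[i];
        }
        double s = los[fi] +
                   rng_u01(seed, step, 11, mid, 4) * (his[fi] - los[fi]);
        if (head_a) { m.st = 1; m.fa = fi; m.sa = s; }
        else { m.st = 2; m.fb = fi; m.sb = s; }
        if (ev) ev->push(step, (int)k, 1, head_a ? 1 : 2, fi, s, NA_REAL);
      } else if (m.st == 1 || m.st == 2) {
        bool is_a = (m.st == 1);
        int fbound = is_a ? m.fa : m.fb;
        double sbound = is_a ? m.sa : m.sb;
        bool perm = is_a ? sp.perm_a : sp.perm_b;
        // bound head unbinds at the force-independent rate ko_s
        double p_off = perm ? 0.0 : 1.0 - std::exp(-sp.ko_s * h);
        bool f_off = rng_u01(seed, step, 12, mid, 0) < p_off;
        // free head S->D integral over nearby filaments
        Vec3 a = fils[fbound].point(sbound);
        double rad_a = 0.5 * fils[fbound].D;
        std::vector<BindGrid> grids_own;
        const std::vector<BindGrid>* grids_ptr = &grids_own;
        double tot = 0.0;
        bool use_cache = cache_binding && s2d_cache[k].valid &&
                         s2d_cache[k].f == fbound &&
                         s2d_cache[k].s == sbound;
        if (use_cache) {
          tot = s2d_cache[k].tot;
          grids_ptr = &s2d_cache[k].grids;
        } else {
          double wband = (sp.kappa > 0.0)
                             ? std::sqrt(2.0 * ecut / (beta * sp.kappa))
                             : 1e30;
          double reach_pt = sp.ell0 + wband;
          for (int j = 0; j < nfil; ++j) {
            if (j == fbound && !sp.allow_same) continue;
            if (sp.bind_mobile_only && !fils[j].mobile) continue;
            double rad_sum = rad_a + 0.5 * fils[j].D;
            Vec3 dc = min_image(fils[j].x - a, bd);
            double rmax = 0.5 * fils[j].L + rad_sum + reach_pt;
            if (dc.dot(dc) > rmax * rmax) continue;
            BindGrid g;
            g.fil = j;
            if (s2d_grid(a, fils[j], rad_sum, sp, beta, bd, nodes, ecut, g) >
                0.0) {
              tot += g.total;
              grids_own.push_back(std::move(g));
            }
          }
          if (cache_binding) {
            s2d_cache[k].valid = true;
            s2d_cache[k].f = fbound;
            s2d_cache[k].s = sbound;
            s2d_cache[k].tot = tot;
            s2d_cache[k].grids = grids_own;
            grids_ptr = &s2d_cache[k].grids;
          }
        }
        const std::vector<BindGrid>& grids = *grids_ptr;
        double R_on = sp.ko_d * sp.eps * sp.ke * tot;
        double p_on = 1.0 - std::exp(-R_on * h);
        bool f_on = rng_u01(seed, step, 12, mid, 1) < p_on;
        if (f_on && f_off) {
          if (rng_u01(seed, step, 12, mid, 2) < 0.5) f_on = false;
          else f_off = false;
        }
        if (f_off) {
          if (ev) ev->push(step, (int)k, 2, is_a ? 1 : 2, fbound, sbound,
                           NA_REAL);
          detach_head(m, is_a);
        } else if (f_on && tot > 0.0) {
          // inverse-transform on the discretized density
          double u = rng_u01(seed, step, 12, mid, 3) * tot;
          const BindGrid* gg = &grids.back();
          for (const auto& g : grids) {
            if (u <= g.total) { gg = &g; break; }
            u -= g.total;
          }
          int node = (int)gg->w.size() - 1;
          double uu = u;
          for (size_t q = 0; q < gg->w.size(); ++q) {
            if (uu <= gg->w[q]) { node = (int)q; break; }
            uu -= gg->w[q];
          }
          double frac = (gg->w[node] > 0.0) ? uu / gg->w[node] : 0.5;
          double snew = gg->lo + (node + frac) * gg->ds;
          double half = 0.5 * fils[gg->fil].L;
          snew = std::max(-half, std::min(half, snew));
          if (is_a) { m.st = 3; m.fb = gg->fil; m.sb = snew; }
          else { m.st = 3; m.fa = gg->fil; m.sa = snew; }
          double lf; Vec3 nhat, ra, rb, dvec;
          tether_geom(fils, m, bd, lf, nhat, ra, rb, dvec);
          if (ev) ev->push(step, (int)k, 3, is_a ? 2 : 1, gg->fil, snew, lf);
        }
      } else if (m.st == 3) {
        double lf; Vec3 nhat, ra, rb, dvec;
        tether_geom(fils, m, bd, lf, nhat, ra, rb, dvec);
        double e = 0.5 * sp.kappa * (lf - sp.ell0) * (lf - sp.ell0);
        double arg = sp.lambda * beta * e;
        double R = sp.ko_d * ((arg > 700.0) ? std::exp(700.0) : std::exp(arg));
        double p = 1.0 - std::exp(-R * h);
        bool fa = !sp.perm_a && rng_u01(seed, step, 13, mid, 0) < p;
        bool fb = !sp.perm_b && rng_u01(seed, step, 13, mid, 1) < p;
        if (fa && fb) {
          if (rng_u01(seed, step, 13, mid, 2) < 0.5) fb = false;
          else fa = false;
        }
        if (fa || fb) {
          if (ev) ev->push(step, (int)k, 4, fa ? 1 : 2,
                           fa ? m.fa : m.fb, fa ? m.sa : m.sb, lf);
          detach_head(m, fa);
        }
      }
    }
  }

  // ---- brownian kick as an effective non-constraint wrench
  void brownian_wrench(std::vector<Wrench>& F) {
    for (size_t i = 0; i < fils.size(); ++i) {
      if (!fils[i].mobile || !brownian || kbt <= 0.0) continue;
      const Fil& f = fils[i];
      Vec3 e1, e2;
      perp_frame(f.p, e1, e2);
      double g1 = rng_norm(seed, step, 20, i, 0);
      double g2 = rng_norm(seed, step, 20, i, 1);
      double g3 = rng_norm(seed, step, 20, i, 2);
      double g4 = rng_norm(seed, step, 20, i, 3);
      double g5 = rng_norm(seed, step, 20, i, 4);
      double dpar = std::sqrt(2.0 * kbt * h / f.zpar);
      double dperp = std::sqrt(2.0 * kbt * h / f.zperp);
      double drot = std::sqrt(2.0 * kbt * h / f.zrot);
      Vec3 dx = f.p * (dpar * g1) + e1 * (dperp * g2) + e2 * (dperp * g3);
      Vec3 dphi = e1 * (drot * g4) + e2 * (drot * g5);
      // deliver as force so it passes through the implicit solve
      double fpar = dx.dot(f.p);
      Vec3 force = f.p * (fpar * f.zpar / h) +
                   (dx - f.p * fpar) * (f.zperp / h);
      Vec3 torque = dphi * (f.zrot / h);
      F[i].f = F[i].f + force;
      F[i].t = F[i].t + torque;
    }
  }

  // ---- task 3: constraint solve + configuration advance
  Diag filament_step(std::vector<Con>& cons, std::vector<double>& gamma) {
    int n = fils.size();
    cons.clear();
    collect_collisions_impl(fils, bd, buffer, cons);
    size_t n_uni = cons.size();
    collect_tethers_impl(fils, motors, species, bd, cons);
    size_t nc = cons.size();
    Diag dg;
    dg.nu = (int)n_uni; dg.nb = (int)(nc - n_uni);
    dg.min_sep = std::numeric_limits<double>::infinity();
    for (size_t k = 0; k < n_uni; ++k)
      dg.min_sep = std::min(dg.min_sep, cons[k].phi);

    std::vector<Wrench> Fnc(n);
    brownian_wrench(Fnc);

    QPWork wk;
    wk.F.resize(n);
    wk.U.resize(n);
    std::vector<double> q(nc), dtu(nc);
    apply_mobility(fils, Fnc, wk.U);
    apply_DT(cons, wk.U, dtu);
    for (size_t k = 0; k < nc; ++k) {
      double phi0 = cons[k].bilateral ? (cons[k].phi - cons[k].rest)
                                      : cons[k].phi;
      q[k] = phi0 / h + dtu[k];
    }
    std::vector<bool> uni(nc);
    for (size_t k = 0; k < nc; ++k) uni[k] = !cons[k].bilateral;
    double qmax = 0.0;
    for (size_t k = 0; k < nc; ++k) qmax = std::max(qmax, std::fabs(q[k]));
    double tol = tol_rel * std::max(1.0, qmax);
    dg.tol_abs = tol;
    QPOps ops;
    ops.build(fils, cons, h);
    auto mv = [&](const std::vector<double>& g, std::vector<double>& y) {
      ops.matvec(g, y);
    };
    gamma.assign(nc, 0.0);
    for (size_t k = 0; k < nc; ++k) {
      auto& map = cons[k].bilateral ? warm_bil : warm_uni;
      auto it = map.find(cons[k].key);
      if (it != map.end()) {
        // linear prediction from the two previous solves
        double g0 = 2.0 * it->second.cur - it->second.prev;
        if (!cons[k].bilateral && g0 < 0.0) g0 = 0.0;
        gamma[k] = g0;
      } else if (cons[k].bilateral && cons[k].kinv > 0.0) {
        // fresh tether: spring force at current geometry
        gamma[k] = -(cons[k].phi - cons[k].rest) / cons[k].kinv;
      }
    }
    int sweeps = pgs_smooth_ops(ops, q, uni, tol, pgs_sweeps, gamma,
                                dg.pg_resid);
    // the smoother's in-sweep residual is stale; BBPGD re-evaluates the
    // true projected gradient and returns immediately if converged
    dg.iters = sweeps +
        bbpgd(mv, q, uni, tol, maxit, gamma, dg.pg_resid, &ops.diag);
    {
      std::unordered_map<long, Warm> new_uni, new_bil;
      for (size_t k = 0; k < nc; ++k) {
        auto& old_map = cons[k].bilateral ? warm_bil : warm_uni;
        auto& new_map = cons[k].bilateral ? new_bil : new_uni;
        auto it = old_map.find(cons[k].key);
        double prev = (it != old_map.end()) ? it->second.cur : gamma[k];
        new_map[cons[k].key] = Warm{gamma[k], prev};
      }
      warm_uni.swap(new_uni);
      warm_bil.swap(new_bil);
    }

    // total velocity and residual diagnostics
    std::vector<Wrench> Ftot(n);
    apply_D(cons, gamma, Ftot);
    for (int i = 0; i < n; ++i) {
      Ftot[i].f = Ftot[i].f + Fnc[i].f;
      Ftot[i].t = Ftot[i].t + Fnc[i].t;
    }
    std::vector<Twist> U(n);
    apply_mobility(fils, Ftot, U);
    apply_DT(cons, U, dtu);
    dg.comp_resid = 0.0;
    dg.bil_resid = 0.0;
    for (size_t k = 0; k < nc; ++k) {
      if (cons[k].bilateral) {
        double philin = cons[k].phi + h * dtu[k] - cons[k].rest;
        double r = (cons[k].kinv > 0.0)
                       ? philin / cons[k].kinv + gamma[k]
                       : philin;  // rigid joint: gap itself must vanish
        // scale to the gradient units used by the solver tolerance
        double rg = (cons[k].kinv > 0.0) ? r * cons[k].kinv / h : r / h;
        dg.bil_resid = std::max(dg.bil_resid, std::fabs(rg));
      } else {
        double philin = cons[k].phi + h * dtu[k];
        dg.comp_resid = std::max(
            dg.comp_resid, std::fabs(std::min(gamma[k], philin / h)));
      }
    }

    // advance configuration
    for (int i = 0; i < n; ++i) {
      if (!fils[i].mobile) continue;
      fils[i].x = fils[i].x + U[i].v * h;
      fils[i].q = qmul(qexp(U[i].w * h), fils[i].q);
      if (bd.kind == 1) {
        fils[i].x.x = wrap1(fils[i].x.x, bd.bx, images[i][0]);
        fils[i].x.y = wrap1(fils[i].x.y, bd.by, images[i][1]);
        fils[i].x.z = wrap1(fils[i].x.z, bd.bz, images[i][2]);
      } else if (bd.kind == 2) {
        fils[i].x.x = wrap1(fils[i].x.x, bd.bx, images[i][0]);
      }
      fils[i].refresh(eta);
      if (!std::isfinite(fils[i].x.x) || !std::isfinite(fils[i].q.w))
        stop("non-finite filament state at step %ld", step);
    }
    return dg;
  }

  // stress from the last solve: sigma = (1/V) sum f (x) d
  void stress(const std::vector<Con>& cons, const std::vector<double>& gamma,
              double sig_col[9], double sig_xl[9]) {
    for (int i = 0; i < 9; ++i) { sig_col[i] = 0.0; sig_xl[i] = 0.0; }
    for (size_t k = 0; k < cons.size(); ++k) {
      const Con& c = cons[k];
      if (c.j < 0) continue;  // wall constraints are external
      Vec3 f = c.n * gamma[k];
      double* s = c.bilateral ? sig_xl : sig_col;
      s[0] += f.x * c.d.x; s[1] += f.x * c.d.y; s[2] += f.x * c.d.z;
      s[3] += f.y * c.d.x; s[4] += f.y * c.d.y; s[5] += f.y * c.d.z;
      s[6] += f.z * c.d.x; s[7] += f.z * c.d.y; s[8] += f.z * c.d.z;
    }
  }
};

// ------------------------------------------------------------- R marshalling

static Engine make_engine(NumericMatrix fil, IntegerMatrix img,
                          NumericMatrix mot, NumericMatrix spe,
                          NumericVector boundary, List cfg) {
  Engine e;
  e.eta = as<double>(cfg["eta"]);
  e.fils = parse_fils(fil, e.eta);
  e.images.resize(fil.nrow());
  for (int i = 0; i < img.nrow(); ++i)
    e.images[i] = {img(i, 0), img(i, 1), img(i, 2)};
  e.motors = parse_motors(mot);
  e.species = parse_species(spe);
  e.bd = parse_boundary(boundary);
  e.h = as<double>(cfg["h"]);
  e.kbt = as<double>(cfg["kbt"]);
  e.brownian = as<bool>(cfg["brownian"]);
  e.buffer = as<double>(cfg["buffer"]);
  e.tol_rel = as<double>(cfg["tol"]);
  e.maxit = as<int>(cfg["maxit"]);
  e.nodes = as<int>(cfg["nodes"]);
  e.pgs_sweeps = cfg.containsElementNamed("pgs_sweeps") ? as<int>(cfg["pgs_sweeps"]) : 20;
  e.cache_binding = cfg.containsElementNamed("cache_binding") &&
                    as<bool>(cfg["cache_binding"]);
  e.s2d_cache.resize(e.motors.size());
  e.ecut = as<double>(cfg["ecut"]);
  e.seed = (uint64_t)as<double>(cfg["seed"]);
  e.step = (long)as<double>(cfg["step"]);
  e.time = as<double>(cfg["time"]);
  if (e.h <= 0) stop("timestep h must be positive");
  for (auto& m : e.motors) {
    if (m.sp < 0 || m.sp >= (int)e.species.size())
      stop("motor species index out of range");
  }
  return e;
}

static IntegerMatrix images_to_matrix(const Engine& e) {
  IntegerMatrix img(e.images.size(), 3);
  for (size_t i = 0; i < e.images.size(); ++i) {
    img(i, 0) = e.images[i][0];
    img(i, 1) = e.images[i][1];
    img(i, 2) = e.images[i][2];
  }
  return img;
}

// [[Rcpp::export]]
NumericMatrix cpp_directors(NumericMatrix quat) {
  NumericMatrix out(quat.nrow(), 3);
  for (int i = 0; i < quat.nrow(); ++i) {
    Quat q(quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3));
    double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
    if (std::fabs(n - 1.0) > 1e-6)
      stop("quaternion %d is not normalized (|q| = %g)", i + 1, n);
    q.normalize();
    Vec3 p = q.director();
    out(i, 0) = p.x; out(i, 1) = p.y; out(i, 2) = p.z;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_min_distance(NumericVector f1, NumericVector f2,
                      NumericVector boundary) {
  Boundary bd = parse_boundary(boundary);
  Fil a, b;
  a.x = Vec3(f1[0], f1[1], f1[2]); a.q = Quat(f1[3], f1[4], f1[5], f1[6]);
  a.L = f1[7]; a.D = f1[8]; a.mobile = true; a.refresh(1.0);
  b.x = Vec3(f2[0], f2[1], f2[2]); b.q = Quat(f2[3], f2[4], f2[5], f2[6]);
  b.L = f2[7]; b.D = f2[8]; b.mobile = true; b.refresh(1.0);
  Vec3 dc = min_image(b.x - a.x, bd);
  Vec3 cb = a.x + dc;
  double s1, s2, dist;
  Vec3 nhat;
  seg_seg(a.x, a.p, 0.5 * a.L, cb, b.p, 0.5 * b.L, s1, s2, dist, nhat);
  double sep = dist - 0.5 * (a.D + b.D);
  return List::create(_["sep"] = sep, _["s1"] = s1, _["s2"] = s2,
                      _["n"] = NumericVector::create(nhat.x, nhat.y, nhat.z));
}

// [[Rcpp::export]]
NumericMatrix cpp_mobility_apply(NumericMatrix fil, double eta,
                                 NumericMatrix F) {
  std::vector<Fil> fs = parse_fils(fil, eta);
  NumericMatrix U(F.nrow(), 6);
  for (int i = 0; i < (int)fs.size(); ++i) {
    Wrench w;
    w.f = Vec3(F(i, 0), F(i, 1), F(i, 2));
    w.t = Vec3(F(i, 3), F(i, 4), F(i, 5));
    Twist u = mobility_one(fs[i], w);
    U(i, 0) = u.v.x; U(i, 1) = u.v.y; U(i, 2) = u.v.z;
    U(i, 3) = u.w.x; U(i, 4) = u.w.y; U(i, 5) = u.w.z;
  }
  return U;
}

// [[Rcpp::export]]
List cpp_advance_configuration(NumericMatrix fil, IntegerMatrix img,
                               NumericMatrix U, double h, double eta,
                               NumericVector boundary) {
  Boundary bd = parse_boundary(boundary);
  std::vector<Fil> fs = parse_fils(fil, eta);
  std::vector<std::array<int, 3>> ims(fs.size());
  for (size_t i = 0; i < fs.size(); ++i)
    ims[i] = {img(i, 0), img(i, 1), img(i, 2)};
  for (size_t i = 0; i < fs.size(); ++i) {
    if (!fs[i].mobile) continue;
    for (int c = 0; c < 6; ++c)
      if (!std::isfinite(U(i, c))) stop("non-finite velocity for filament %d",
                                        (int)i + 1);
    fs[i].x = fs[i].x + Vec3(U(i, 0), U(i, 1), U(i, 2)) * h;
    fs[i].q = qmul(qexp(Vec3(U(i, 3), U(i, 4), U(i, 5)) * h), fs[i].q);
    if (bd.kind == 1) {
      fs[i].x.x = wrap1(fs[i].x.x, bd.bx, ims[i][0]);
      fs[i].x.y = wrap1(fs[i].x.y, bd.by, ims[i][1]);
      fs[i].x.z = wrap1(fs[i].x.z, bd.bz, ims[i][2]);
    } else if (bd.kind == 2) {
      fs[i].x.x = wrap1(fs[i].x.x, bd.bx, ims[i][0]);
    }
    fs[i].refresh(eta);
  }
  IntegerMatrix img2(fs.size(), 3);
  for (size_t i = 0; i < fs.size(); ++i) {
    img2(i, 0) = ims[i][0]; img2(i, 1) = ims[i][1]; img2(i, 2) = ims[i][2];
  }
  return List::create(_["fil"] = fils_to_matrix(fs), _["img"] = img2);
}

// [[Rcpp::export]]
NumericMatrix cpp_wrap_points(NumericMatrix x, NumericVector boundary) {
  Boundary bd = parse_boundary(boundary);
  NumericMatrix out(x.nrow(), 3);
  for (int i = 0; i < x.nrow(); ++i) {
    Engine e;
    e.bd = bd;
    Vec3 v = e.wrap_vec(Vec3(x(i, 0), x(i, 1), x(i, 2)));
    out(i, 0) = v.x; out(i, 1) = v.y; out(i, 2) = v.z;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_min_image(NumericMatrix d, NumericVector boundary) {
  Boundary bd = parse_boundary(boundary);
  NumericMatrix out(d.nrow(), 3);
  for (int i = 0; i < d.nrow(); ++i) {
    Vec3 v = min_image(Vec3(d(i, 0), d(i, 1), d(i, 2)), bd);
    out(i, 0) = v.x; out(i, 1) = v.y; out(i, 2) = v.z;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_wall_gaps(NumericVector f, NumericVector boundary) {
  Boundary bd = parse_boundary(boundary);
  Fil a;
  a.x = Vec3(f[0], f[1], f[2]); a.q = Quat(f[3], f[4], f[5], f[6]);
  a.L = f[7]; a.D = f[8]; a.mobile = true; a.refresh(1.0);
  std::vector<Con> cons;
  wall_contacts(a, 0, bd, std::numeric_limits<double>::infinity(), cons);
  NumericMatrix out(cons.size(), 7);
  for (size_t k = 0; k < cons.size(); ++k) {
    Vec3 pt = a.x + cons[k].ri;
    out(k, 0) = cons[k].phi;
    out(k, 1) = pt.x; out(k, 2) = pt.y; out(k, 3) = pt.z;
    out(k, 4) = cons[k].n.x; out(k, 5) = cons[k].n.y; out(k, 6) = cons[k].n.z;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_seg_in_sphere(NumericVector c, NumericVector p, double L,
                         NumericVector x, double rc) {
  double lo, hi;
  return seg_in_sphere(Vec3(c[0], c[1], c[2]), Vec3(p[0], p[1], p[2]), L,
                       Vec3(x[0], x[1], x[2]), rc, lo, hi);
}

// [[Rcpp::export]]
List cpp_rate_u2s(NumericVector x, NumericMatrix fil, NumericVector spec,
                  NumericVector boundary) {
  Boundary bd = parse_boundary(boundary);
  std::vector<Fil> fs = parse_fils(fil, 1.0);
  NumericMatrix sm(1, spec.size());
  for (int i = 0; i < spec.size(); ++i) sm(0, i) = spec[i];
  Species sp = parse_species(sm)[0];
  Vec3 xm(x[0], x[1], x[2]);
  NumericVector lin(fs.size());
  double linsum = 0.0;
  for (size_t i = 0; i < fs.size(); ++i) {
    Vec3 dc = min_image(fs[i].x - xm, bd);
    Vec3 ci = xm + dc;
    double lo, hi;
    lin[i] = seg_in_sphere(ci, fs[i].p, fs[i].L, xm, sp.rc, lo, hi);
    linsum += lin[i];
  }
  double R = sp.ko_s * 3.0 * sp.eps * sp.ka /
             (4.0 * M_PI * sp.rc * sp.rc * sp.rc) * linsum;
  return List::create(_["rate"] = R, _["lin"] = lin);
}

// [[Rcpp::export]]
List cpp_rate_s2d(NumericVector a_pt, double rad_a, IntegerVector exclude,
                  NumericMatrix fil, NumericVector spec, NumericVector boundary,
                  double kbt, int nodes, double ecut) {
  Boundary bd = parse_boundary(boundary);
  std::vector<Fil> fs = parse_fils(fil, 1.0);
  NumericMatrix sm(1, spec.size());
  for (int i = 0; i < spec.size(); ++i) sm(0, i) = spec[i];
  Species sp = parse_species(sm)[0];
  Vec3 a(a_pt[0], a_pt[1], a_pt[2]);
  double beta = 1.0 / kbt;
  std::vector<bool> excl(fs.size(), false);
  for (int i = 0; i < exclude.size(); ++i)
    if (exclude[i] >= 1 && exclude[i] <= (int)fs.size())
      excl[exclude[i] - 1] = true;
  double tot = 0.0;
  List grids;
  for (size_t j = 0; j < fs.size(); ++j) {
    if (excl[j]) continue;
    BindGrid g;
    g.fil = (int)j;
    double rad_sum = rad_a + 0.5 * fs[j].D;
    if (s2d_grid(a, fs[j], rad_sum, sp, beta, bd, nodes, ecut, g) > 0.0) {
      tot += g.total;
      NumericVector s_nodes(g.w.size()), w(g.w.size());
      for (size_t q = 0; q < g.w.size(); ++q) {
        s_nodes[q] = g.lo + (q + 0.5) * g.ds;
        w[q] = g.w[q] / g.ds;  // density, not node mass
      }
      grids.push_back(List::create(_["fil"] = (int)j + 1, _["s"] = s_nodes,
                                   _["density"] = w, _["ds"] = g.ds));
    }
  }
  double R = sp.ko_d * sp.eps * sp.ke * tot;
  return List::create(_["rate"] = R, _["grids"] = grids);
}

// Constraint list -> R matrix (19 columns; see R wrapper for names)
static NumericMatrix cons_to_matrix(const std::vector<Con>& cons) {
  NumericMatrix out(cons.size(), 19);
  for (size_t k = 0; k < cons.size(); ++k) {
    const Con& c = cons[k];
    out(k, 0) = c.bilateral ? 1.0 : 0.0;
    out(k, 1) = c.i + 1;
    out(k, 2) = c.j + 1;  // 0 means wall
    out(k, 3) = c.phi; out(k, 4) = c.rest; out(k, 5) = c.kinv;
    out(k, 6) = c.n.x; out(k, 7) = c.n.y; out(k, 8) = c.n.z;
    out(k, 9) = c.ri.x; out(k, 10) = c.ri.y; out(k, 11) = c.ri.z;
    out(k, 12) = c.rj.x; out(k, 13) = c.rj.y; out(k, 14) = c.rj.z;
    out(k, 15) = c.d.x; out(k, 16) = c.d.y; out(k, 17) = c.d.z;
    out(k, 18) = c.motor + 1;
  }
  return out;
}

static std::vector<Con> cons_from_matrix(const NumericMatrix& cm) {
  std::vector<Con> cons(cm.nrow());
  for (int k = 0; k < cm.nrow(); ++k) {
    Con& c = cons[k];
    c.bilateral = cm(k, 0) != 0.0;
    c.i = (int)cm(k, 1) - 1;
    c.j = (int)cm(k, 2) - 1;
    c.phi = cm(k, 3); c.rest = cm(k, 4); c.kinv = cm(k, 5);
    c.n = Vec3(cm(k, 6), cm(k, 7), cm(k, 8));
    c.ri = Vec3(cm(k, 9), cm(k, 10), cm(k, 11));
    c.rj = Vec3(cm(k, 12), cm(k, 13), cm(k, 14));
    c.d = Vec3(cm(k, 15), cm(k, 16), cm(k, 17));
    c.motor = (int)cm(k, 18) - 1;
  }
  return cons;
}

// [[Rcpp::export]]
NumericMatrix cpp_collect_collisions(NumericMatrix fil, NumericVector boundary,
                                     double buffer) {
  Boundary bd = parse_boundary(boundary);
  std::vector<Fil> fs = parse_fils(fil, 1.0);
  std::vector<Con> cons;
  collect_collisions_impl(fs, bd, buffer, cons);
  return cons_to_matrix(cons);
}

// [[Rcpp::export]]
NumericMatrix cpp_collect_tethers(NumericMatrix fil, NumericMatrix mot,
                                  NumericMatrix spe, NumericVector boundary) {
  Boundary bd = parse_boundary(boundary);
  std::vector<Fil> fs = parse_fils(fil, 1.0);
  std::vector<Motor> ms = parse_motors(mot);
  std::vector<Species> sp = parse_species(spe);
  std::vector<Con> cons;
  collect_tethers_impl(fs, ms, sp, bd, cons);
  return cons_to_matrix(cons);
}

// Dense QP assembly (for tests and small problems): M and q of the per-step
// convex program, rows ordered as in the constraint matrix.
// [[Rcpp::export]]
List cpp_qp_dense(NumericMatrix fil, double eta, NumericMatrix conmat,
                  double h, NumericMatrix Fnc) {
  std::vector<Fil> fs = parse_fils(fil, eta);
  std::vector<Con> cons = cons_from_matrix(conmat);
  size_t nc = cons.size();
  int n = fs.size();
  QPWork wk;
  wk.F.resize(n); wk.U.resize(n);
  NumericMatrix M(nc, nc);
  std::vector<double> g(nc, 0.0), y(nc);
  for (size_t k = 0; k < nc; ++k) {
    g.assign(nc, 0.0);
    g[k] = 1.0;
    qp_matvec(fs, cons, h, g, y, wk);
    for (size_t r = 0; r < nc; ++r) M(r, k) = y[r];
  }
  std::vector<Wrench> F(n);
  for (int i = 0; i < n; ++i) {
    F[i].f = Vec3(Fnc(i, 0), Fnc(i, 1), Fnc(i, 2));
    F[i].t = Vec3(Fnc(i, 3), Fnc(i, 4), Fnc(i, 5));
  }
  std::vector<Twist> U(n);
  apply_mobility(fs, F, U);
  std::vector<double> dtu(nc);
  apply_DT(cons, U, dtu);
  NumericVector q(nc);
  for (size_t k = 0; k < nc; ++k) {
    double phi0 = cons[k].bilateral ? (cons[k].phi - cons[k].rest)
                                    : cons[k].phi;
    q[k] = phi0 / h + dtu[k];
  }
  return List::create(_["M"] = M, _["q"] = q);
}

// [[Rcpp::export]]
List cpp_bbpgd_dense(NumericMatrix M, NumericVector q, int nu, double tol,
                     int maxit) {
  size_t n = q.size();
  std::vector<double> qv(q.begin(), q.end());
  std::vector<bool> uni(n, false);
  for (int i = 0; i < nu; ++i) uni[i] = true;
  auto mv = [&](const std::vector<double>& g, std::vector<double>& y) {
    for (size_t r = 0; r < n; ++r) {
      double acc = 0.0;
      for (size_t c = 0; c < n; ++c) acc += M(r, c) * g[c];
      y[r] = acc;
    }
  };
  std::vector<double> gamma;
  double resid;
  int it = bbpgd(mv, qv, uni, tol, maxit, gamma, resid);
  return List::create(_["gamma"] = NumericVector(gamma.begin(), gamma.end()),
                      _["iters"] = it, _["resid"] = resid,
                      _["converged"] = resid <= tol);
}

// [[Rcpp::export]]
NumericMatrix cpp_constraint_forces(NumericMatrix fil, NumericMatrix conmat,
                                    NumericVector gamma) {
  std::vector<Fil> fs = parse_fils(fil, 1.0);
  std::vector<Con> cons = cons_from_matrix(conmat);
  std::vector<double> g(gamma.begin(), gamma.end());
  std::vector<Wrench> F(fs.size());
  apply_D(cons, g, F);
  NumericMatrix out(fs.size(), 6);
  for (size_t i = 0; i < fs.size(); ++i) {
    out(i, 0) = F[i].f.x; out(i, 1) = F[i].f.y; out(i, 2) = F[i].f.z;
    out(i, 3) = F[i].t.x; out(i, 4) = F[i].t.y; out(i, 5) = F[i].t.z;
  }
  return out;
}

// Brownian kick as an effective non-constraint wrench (the exact draws the
// engine would use at this state's seed/step).
// [[Rcpp::export]]
NumericMatrix cpp_brownian_wrench(NumericMatrix fil, IntegerMatrix img,
                                  NumericVector boundary, List cfg) {
  NumericMatrix mot(0, 9), spe(0, 21);
  Engine e = make_engine(fil, img, mot, spe, boundary, cfg);
  std::vector<Wrench> F(e.fils.size());
  e.brownian_wrench(F);
  NumericMatrix out(e.fils.size(), 6);
  for (size_t i = 0; i < e.fils.size(); ++i) {
    out(i, 0) = F[i].f.x; out(i, 1) = F[i].f.y; out(i, 2) = F[i].f.z;
    out(i, 3) = F[i].t.x; out(i, 4) = F[i].t.y; out(i, 5) = F[i].t.z;
  }
  return out;
}

// One step with selectable tasks (module-level surface; the full run loop
// below is the production path). Does not advance the step counter; the R
// wrapper owns RNG-stream bookkeeping.
// [[Rcpp::export]]
List cpp_step_tasks(NumericMatrix fil, IntegerMatrix img, NumericMatrix mot,
                    NumericMatrix spe, NumericVector boundary, List cfg,
                    bool do_move, bool do_kmc, bool do_filament) {
  Engine e = make_engine(fil, img, mot, spe, boundary, cfg);
  List out;
  if (do_move) e.motor_move();
  if (do_kmc) e.kmc();
  if (do_filament) {
    std::vector<Con> cons;
    std::vector<double> gamma;
    Diag dg = e.filament_step(cons, gamma);
    double sc[9], sx[9];
    e.stress(cons, gamma, sc, sx);
    out = List::create(
        _["constraints"] = cons_to_matrix(cons),
        _["gamma"] = NumericVector(gamma.begin(), gamma.end()),
        _["n_unilateral"] = dg.nu, _["n_bilateral"] = dg.nb,
        _["iterations"] = dg.iters, _["pg_residual"] = dg.pg_resid,
        _["comp_residual"] = dg.comp_resid, _["bil_residual"] = dg.bil_resid,
        _["min_separation"] = dg.min_sep, _["tol_abs"] = dg.tol_abs,
        _["sigma_col"] = NumericVector(sc, sc + 9),
        _["sigma_xl"] = NumericVector(sx, sx + 9));
  }
  out["fil"] = fils_to_matrix(e.fils);
  out["img"] = images_to_matrix(e);
  out["motors"] = motors_to_matrix(e.motors);
  return out;
}

// ------------------------------------------------------------- full run loop

// [[Rcpp::export]]
List cpp_run(NumericMatrix fil, IntegerMatrix img, NumericMatrix mot,
             NumericMatrix spe, NumericVector boundary, List cfg, int nsteps,
             int record_every, bool record_motors, bool record_events,
             double max_events) {
  Engine e = make_engine(fil, img, mot, spe, boundary, cfg);
  EventLog ev;
  ev.cap = (size_t)max_events;
  if (record_events) e.ev = &ev;

  int n = e.fils.size();
  std::vector<Con> cons;
  std::vector<double> gamma;

  List frames;
  std::vector<double> lg_step, lg_time, lg_nu, lg_nb, lg_iters, lg_resid,
      lg_comp, lg_bil, lg_minsep, lg_tol;

  auto record_frame = [&](const Diag* dgp) {
    NumericMatrix fm(n, 7);
    IntegerMatrix im(n, 3);
    for (int i = 0; i < n; ++i) {
      fm(i, 0) = e.fils[i].x.x; fm(i, 1) = e.fils[i].x.y;
      fm(i, 2) = e.fils[i].x.z;
      fm(i, 3) = e.fils[i].q.w; fm(i, 4) = e.fils[i].q.x;
      fm(i, 5) = e.fils[i].q.y; fm(i, 6) = e.fils[i].q.z;
      im(i, 0) = e.images[i][0]; im(i, 1) = e.images[i][1];
      im(i, 2) = e.images[i][2];
    }
    double sc[9], sx[9];
    if (dgp) e.stress(cons, gamma, sc, sx);
    else for (int i = 0; i < 9; ++i) { sc[i] = 0; sx[i] = 0; }
    List fr = List::create(
        _["step"] = (double)e.step, _["time"] = e.time, _["fil"] = fm,
        _["img"] = im,
        _["sigma_col"] = NumericVector(sc, sc + 9),
        _["sigma_xl"] = NumericVector(sx, sx + 9));
    if (record_motors) fr["motors"] = motors_to_matrix(e.motors);
    frames.push_back(fr);
  };

  if (record_every > 0) record_frame(nullptr);

  bool any_active = false, any_mobile = false;
  for (const auto& sp : e.species) {
    if (sp.vm > 0.0 && (sp.active_a || sp.active_b)) any_active = true;
  }
  for (const auto& f : e.fils) {
    if (f.mobile) any_mobile = true;
  }
  for (int k = 0; k < nsteps; ++k) {
    if (any_active) e.motor_move();
    e.kmc();
    Diag dg;
    if (any_mobile) {
      dg = e.filament_step(cons, gamma);
    } else {
      dg = Diag{0, 0, 0, 0.0, 0.0, 0.0,
                std::numeric_limits<double>::infinity(), 0.0};
    }
    e.step += 1;
    e.time += e.h;
    lg_step.push_back((double)e.step); lg_time.push_back(e.time);
    lg_nu.push_back(dg.nu); lg_nb.push_back(dg.nb);
    lg_iters.push_back(dg.iters); lg_resid.push_back(dg.pg_resid);
    lg_comp.push_back(dg.comp_resid); lg_bil.push_back(dg.bil_resid);
    lg_minsep.push_back(dg.min_sep); lg_tol.push_back(dg.tol_abs);
    if (record_every > 0 && ((k + 1) % record_every == 0 || k == nsteps - 1))
      record_frame(&dg);
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List log = List::create(
      _["step"] = NumericVector(lg_step.begin(), lg_step.end()),
      _["time"] = NumericVector(lg_time.begin(), lg_time.end()),
      _["n_unilateral"] = NumericVector(lg_nu.begin(), lg_nu.end()),
      _["n_bilateral"] = NumericVector(lg_nb.begin(), lg_nb.end()),
      _["iterations"] = NumericVector(lg_iters.begin(), lg_iters.end()),
      _["pg_residual"] = NumericVector(lg_resid.begin(), lg_resid.end()),
      _["comp_residual"] = NumericVector(lg_comp.begin(), lg_comp.end()),
      _["bil_residual"] = NumericVector(lg_bil.begin(), lg_bil.end()),
      _["min_separation"] = NumericVector(lg_minsep.begin(), lg_minsep.end()),
      _["tol_abs"] = NumericVector(lg_tol.begin(), lg_tol.end()));

  List out = List::create(
      _["fil"] = fils_to_matrix(e.fils), _["img"] = images_to_matrix(e),
      _["motors"] = motors_to_matrix(e.motors), _["step"] = (double)e.step,
      _["time"] = e.time, _["frames"] = frames, _["log"] = log);
  if (record_events) {
    size_t ne = ev.step.size();
    NumericMatrix em(ne, 7);
    for (size_t i = 0; i < ne; ++i) {
      em(i, 0) = ev.step[i]; em(i, 1) = ev.motor[i]; em(i, 2) = ev.code[i];
      em(i, 3) = ev.head[i]; em(i, 4) = ev.fil[i]; em(i, 5) = ev.s[i];
      em(i, 6) = ev.lf[i];
    }
    out["events"] = em;
    out["events_overflow"] = ev.overflow;
  }
  return out;
}
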