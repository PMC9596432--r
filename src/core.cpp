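// Rigid-body Langevin dynamics core for adhesin-patterned cells.
//
// Each cell is a rigid molecule: one body sphere (B, radius sigma_B) at the
// center plus n adhesin spheres (P, radius sigma_P) at fixed body-frame
// offsets of length `contact_radius`.  Interactions: WCA (truncated-shifted
// LJ) repulsion for B-B and B-P, soft cosine attraction A[1+cos(pi r/r_c)]
// for P-P between distinct cells.  Integration: BAOAB Langevin splitting for
// translation and rotation (isotropic scalar inertia), quaternion
// orientations renormalized each update.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic RNG: xoshiro256++ seeded by splitmix64, Marsaglia polar
// normals.  Independent of R's RNG so that trajectories are bit-reproducible
// from the integer seed alone.
struct Rng {
  uint64_t s[4];
  // ziggurat tables (Marsaglia & Tsang, 128 layers)
  uint32_t kn[128];
  double wn[128], fn[128];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
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
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(next() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      uint64_t ahz = (hz < 0) ? (uint64_t)(-(int64_t)hz) : (uint64_t)hz;
      if (ahz < kn[iz]) return hz * wn[iz];
      const double r = 3.442619855899;
      if (iz == 0) {  // tail
        double xx, yy;
        do {
          xx = -std::log(unif()) / r;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return (hz > 0) ? r + xx : -r - xx;
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

struct Params {
  double sB, sP, eps, A, rc, fcap;
  double s2BB, s2BP;       // (sigma_X+sigma_Y)^2
  double cut2BB, cut2BP;   // squared WCA cutoffs
};

static Params make_params(List p) {
  Params q;
  q.sB  = as<double>(p["sigma_B"]);
  q.sP  = as<double>(p["sigma_P"]);
  q.eps = as<double>(p["epsilon"]);
  q.A   = as<double>(p["A"]);
  q.rc  = as<double>(p["r_c"]);
  q.fcap = as<double>(p["force_cap"]);
  double sBB = 2.0 * q.sB, sBP = q.sB + q.sP;
  q.s2BB = sBB * sBB; q.s2BP = sBP * sBP;
  double c = std::cbrt(2.0);  // 2^{1/3} = (2^{1/6})^2
  q.cut2BB = c * q.s2BB; q.cut2BP = c * q.s2BP;
  return q;
}

// WCA force/r (force on i for rvec = r_i - r_j), accumulates shifted energy.
// Caller guarantees r2 < cutoff^2.
static inline double wca_f(double r2, double s2, double eps, double fcap,
                           double &E) {
  if (r2 < 1e-12) r2 = 1e-12;
  double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
  E += eps + 4.0 * eps * (sr12 - sr6);
  double f = 24.0 * eps * (2.0 * sr12 - sr6) / r2;
  if (f * f * r2 > fcap * fcap) f = fcap / std::sqrt(r2);
  return f;
}

// sin and cos of x in [0, pi] via shifted Taylor series (|err| < 1e-9),
// avoiding two libm calls in the innermost bond loop
static inline void sincos_0pi(double x, double &s, double &c) {
  double t = x - M_PI_2;  // in [-pi/2, pi/2]
  double t2 = t * t;
  double st = t * (1.0 + t2 * (-1.0 / 6 + t2 * (1.0 / 120 + t2 * (-1.0 / 5040 +
              t2 * (1.0 / 362880 + t2 * (-1.0 / 39916800 +
              t2 / 6227020800.0))))));
  double ct = 1.0 + t2 * (-0.5 + t2 * (1.0 / 24 + t2 * (-1.0 / 720 +
              t2 * (1.0 / 40320 + t2 * (-1.0 / 3628800 +
              t2 / 479001600.0)))));
  s = ct;   // sin(x) = cos(x - pi/2)
  c = -st;  // cos(x) = -sin(x - pi/2)
}

// soft cosine P-P force/r; caller guarantees r2 < rc^2
static inline double soft_f(double r2, double A, double rc, double &E) {
  double r = std::sqrt(r2);
  double x = M_PI * r / rc;
  double sx, cx;
  sincos_0pi(x, sx, cx);
  E += A * (1.0 + cx);
  if (r < 1e-9) return A * M_PI * M_PI / (rc * rc);
  return A * M_PI * sx / (rc * r);
}

// minimum image, convention (-L/2, L/2]; assumes |d| < 1.5 L
static inline double mimg(double d, double L) {
  if (d > 0.5 * L) return d - L;
  if (d <= -0.5 * L) return d + L;
  return d;
}

static inline void quat_to_rot(const double *q, double *R) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

struct Engine {
  int N, na;
  std::vector<double> pos, quat, vel, ang;   // 3N, 4N, 3N, 3N
  std::vector<double> loc;                   // 3*na body-frame offsets
  double box[3];
  bool wrap_z;
  Params pp;
  double M, I, cr;                           // mass, scalar inertia, contact radius
  // plates (z walls); active when plates_on
  bool plates_on;
  bool lost;   // a cell jumped an absurd distance in one step
  double zlo, zhi;
  // buffers
  std::vector<double> F, T;                  // 3N force, torque
  std::vector<double> rot;                   // 9N
  std::vector<double> world;                 // 3*na*N adhesin world offsets
  std::vector<char> active;                  // cells needing world coords
  std::vector<int> li, lj;                   // verlet pair list
  std::vector<double> pos0;                  // positions at list build
  double r_int, r_list, skin, prune2, prune_reach2;
  std::vector<double> ska, skb, skva, skvb;  // pair_forces scratch (3*na)
  std::vector<double> locx, locy, locz;      // transposed local coords
  std::vector<double> dots;                  // prune scratch
  // candidate cache: per near pair, adhesin indices that can possibly
  // interact while no cell has moved/rotated more than eps_s/2 since the
  // build; force evaluation still applies the exact cutoffs, so the cache
  // only prunes, never approximates
  std::vector<int> cp_i, cp_j, cs_i, cn_i, cs_j, cn_j;
  std::vector<int> cpool;
  std::vector<double> cpos0, rotacc;
  std::vector<char> cact;
  double eps_s, prune2s, cand_reach2;
  bool cand_valid;
  double energy;

  Engine(NumericMatrix posm, NumericMatrix quatm, NumericMatrix velm,
         NumericMatrix angm, NumericMatrix locm, NumericVector boxv,
         List paramlist, double mass, double inertia, bool wrapz)
      : plates_on(false), lost(false), zlo(0), zhi(0) {
    N = posm.nrow(); na = locm.nrow();
    pp = make_params(paramlist);
    M = mass; I = inertia; wrap_z = wrapz;
    for (int k = 0; k < 3; k++) box[k] = boxv[k];
    pos.resize(3 * N); quat.resize(4 * N); vel.resize(3 * N); ang.resize(3 * N);
    for (int i = 0; i < N; i++)
      for (int k = 0; k < 3; k++) {
        pos[3 * i + k] = posm(i, k);
        vel[3 * i + k] = velm(i, k);
        ang[3 * i + k] = angm(i, k);
      }
    for (int i = 0; i < N; i++)
      for (int k = 0; k < 4; k++) quat[4 * i + k] = quatm(i, k);
    loc.resize(3 * na);
    cr = 0.0;
    for (int a = 0; a < na; a++) {
      double r2 = 0;
      for (int k = 0; k < 3; k++) {
        loc[3 * a + k] = locm(a, k);
        r2 += locm(a, k) * locm(a, k);
      }
      cr = std::max(cr, std::sqrt(r2));
    }
    double cutBP = std::sqrt(pp.cut2BP), cutBB = std::sqrt(pp.cut2BB);
    r_int = std::max(cutBB, std::max(cr + cutBP, 2.0 * cr + pp.rc));
    skin = 3.0;
    r_list = r_int + skin;
    double pt = std::max(cutBP, cr + pp.rc);
    prune2 = pt * pt;
    prune_reach2 = (cr + pt) * (cr + pt);
    ska.resize(3 * na); skb.resize(3 * na);
    skva.resize(3 * na); skvb.resize(3 * na);
    locx.resize(na); locy.resize(na); locz.resize(na);
    for (int a = 0; a < na; a++) {
      locx[a] = loc[3 * a]; locy[a] = loc[3 * a + 1]; locz[a] = loc[3 * a + 2];
    }
    dots.resize(na);
    eps_s = 1.0;
    prune2s = (pt + eps_s) * (pt + eps_s);
    cand_reach2 = (r_int + eps_s) * (r_int + eps_s);
    cpos0.resize(3 * N);
    rotacc.assign(N, 0.0);
    cact.assign(N, 0);
    cand_valid = false;
    F.assign(3 * N, 0.0); T.assign(3 * N, 0.0);
    rot.resize(9 * N); world.resize((size_t)3 * na * N);
    active.assign(N, 0);
    pos0.resize(3 * N);
    build_list();
  }

  inline void dmin(const double *a, const double *b, double *d) const {
    d[0] = mimg(a[0] - b[0], box[0]);
    d[1] = mimg(a[1] - b[1], box[1]);
    d[2] = wrap_z ? mimg(a[2] - b[2], box[2]) : (a[2] - b[2]);
  }

  void build_list() {
    li.clear(); lj.clear();
    double rl2 = r_list * r_list;
    for (int i = 0; i < N; i++)
      for (int j = i + 1; j < N; j++) {
        double d[3];
        dmin(&pos[3 * i], &pos[3 * j], d);
        double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        if (d2 < rl2) { li.push_back(i); lj.push_back(j); }
      }
    pos0 = pos;
  }

  bool need_rebuild(double lim) const {
    double lim2 = lim * lim;
    for (int i = 0; i < N; i++) {
      double d[3];
      dmin(&pos[3 * i], &pos0[3 * i], d);
      if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] > lim2) return true;
    }
    return false;
  }

  bool cand_expired() const {
    double lim = 0.5 * eps_s;
    for (int c = 0; c < N; c++) {
      double d[3];
      dmin(&pos[3 * c], &cpos0[3 * c], d);
      double m = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]) +
                 cr * rotacc[c];
      if (m > lim) return true;
    }
    return false;
  }

  void build_candidates() {
    // list must cover every pair within cand_reach for the cache lifetime
    if (need_rebuild(0.5 * (r_list - std::sqrt(cand_reach2)))) build_list();
    cp_i.clear(); cp_j.clear(); cs_i.clear(); cn_i.clear();
    cs_j.clear(); cn_j.clear(); cpool.clear();
    std::fill(cact.begin(), cact.end(), 0);
    for (int c = 0; c < N; c++) rot_only(c);
    const double *lx = locx.data(), *ly = locy.data(), *lz = locz.data();
    for (size_t m = 0; m < li.size(); m++) {
      int i = li[m], j = lj[m];
      double d[3];
      dmin(&pos[3 * i], &pos[3 * j], d);
      double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (d2 >= cand_reach2) continue;
      cp_i.push_back(i); cp_j.push_back(j);
      const double thr = 0.5 * (prune2s - cr * cr - d2);
      const double *Ri = &rot[9 * i], *Rj = &rot[9 * j];
      double dli[3] = {Ri[0] * d[0] + Ri[3] * d[1] + Ri[6] * d[2],
                       Ri[1] * d[0] + Ri[4] * d[1] + Ri[7] * d[2],
                       Ri[2] * d[0] + Ri[5] * d[1] + Ri[8] * d[2]};
      double dlj[3] = {Rj[0] * d[0] + Rj[3] * d[1] + Rj[6] * d[2],
                       Rj[1] * d[0] + Rj[4] * d[1] + Rj[7] * d[2],
                       Rj[2] * d[0] + Rj[5] * d[1] + Rj[8] * d[2]};
      cs_i.push_back((int)cpool.size());
      int ni = 0;
      for (int a = 0; a < na; a++)
        if (lx[a] * dli[0] + ly[a] * dli[1] + lz[a] * dli[2] < thr) {
          cpool.push_back(a); ni++;
        }
      cn_i.push_back(ni);
      cs_j.push_back((int)cpool.size());
      int nj = 0;
      for (int b = 0; b < na; b++)
        if (lx[b] * dlj[0] + ly[b] * dlj[1] + lz[b] * dlj[2] > -thr) {
          cpool.push_back(b); nj++;
        }
      cn_j.push_back(nj);
      if (ni) cact[i] = 1;
      if (nj) cact[j] = 1;
    }
    cpos0 = pos;
    std::fill(rotacc.begin(), rotacc.end(), 0.0);
    cand_valid = true;
  }

  inline void rot_only(int c) { quat_to_rot(&quat[4 * c], &rot[9 * c]); }

  void world_coords(int c) {
    quat_to_rot(&quat[4 * c], &rot[9 * c]);
    const double *R = &rot[9 * c];
    for (int a = 0; a < na; a++) {
      const double *u = &loc[3 * a];
      double *w = &world[(size_t)3 * (na * (size_t)c + a)];
      w[0] = R[0] * u[0] + R[1] * u[1] + R[2] * u[2];
      w[1] = R[3] * u[0] + R[4] * u[1] + R[5] * u[2];
      w[2] = R[6] * u[0] + R[7] * u[1] + R[8] * u[2];
    }
  }

  // interaction of cached near pair m; candidate adhesin sets are supersets
  // of everything in range, and the exact cutoff tests below decide
  inline void pair_forces(int m) {
    int i = cp_i[m], j = cp_j[m];
    double d[3];
    dmin(&pos[3 * i], &pos[3 * j], d);
    double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    double *Fi = &F[3 * i], *Fj = &F[3 * j];
    double *Ti = &T[3 * i], *Tj = &T[3 * j];
    // B-B
    if (d2 < pp.cut2BB) {
      double f = wca_f(d2, pp.s2BB, pp.eps, pp.fcap, energy);
      for (int k = 0; k < 3; k++) { Fi[k] += f * d[k]; Fj[k] -= f * d[k]; }
    }
    if (d2 >= prune_reach2) return;  // no adhesin of either cell can interact
    const int nka = cn_i[m], nkb = cn_j[m];
    if (nka == 0 && nkb == 0) return;
    const double *Ri = &rot[9 * i], *Rj = &rot[9 * j];
    double *ua = ska.data(), *ub = skb.data();   // world offsets, candidates
    double *va = skva.data(), *vb = skvb.data(); // u_i + d  /  u_j - d
    const int *ia = &cpool[cs_i[m]], *ib = &cpool[cs_j[m]];
    for (int t = 0; t < nka; t++) {
      const double *u = &loc[3 * ia[t]];
      double *w = &ua[3 * t], *v = &va[3 * t];
      w[0] = Ri[0] * u[0] + Ri[1] * u[1] + Ri[2] * u[2];
      w[1] = Ri[3] * u[0] + Ri[4] * u[1] + Ri[5] * u[2];
      w[2] = Ri[6] * u[0] + Ri[7] * u[1] + Ri[8] * u[2];
      v[0] = w[0] + d[0]; v[1] = w[1] + d[1]; v[2] = w[2] + d[2];
    }
    for (int t = 0; t < nkb; t++) {
      const double *u = &loc[3 * ib[t]];
      double *w = &ub[3 * t], *v = &vb[3 * t];
      w[0] = Rj[0] * u[0] + Rj[1] * u[1] + Rj[2] * u[2];
      w[1] = Rj[3] * u[0] + Rj[4] * u[1] + Rj[5] * u[2];
      w[2] = Rj[6] * u[0] + Rj[7] * u[1] + Rj[8] * u[2];
      v[0] = w[0] - d[0]; v[1] = w[1] - d[1]; v[2] = w[2] - d[2];
    }
    // B_i with kept adhesins of j: separation p_jb - c_i = u_jb - d = vb
    for (int m = 0; m < nkb; m++) {
      const double *v = &vb[3 * m];
      double r2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
      if (r2 < pp.cut2BP) {
        double f = wca_f(r2, pp.s2BP, pp.eps, pp.fcap, energy);
        const double *u = &ub[3 * m];
        double fx = f * v[0], fy = f * v[1], fz = f * v[2];
        Fj[0] += fx; Fj[1] += fy; Fj[2] += fz;
        Tj[0] += u[1] * fz - u[2] * fy;
        Tj[1] += u[2] * fx - u[0] * fz;
        Tj[2] += u[0] * fy - u[1] * fx;
        Fi[0] -= fx; Fi[1] -= fy; Fi[2] -= fz;
      }
    }
    // B_j with kept adhesins of i: separation p_ia - c_j = u_ia + d = va
    for (int m = 0; m < nka; m++) {
      const double *v = &va[3 * m];
      double r2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
      if (r2 < pp.cut2BP) {
        double f = wca_f(r2, pp.s2BP, pp.eps, pp.fcap, energy);
        const double *u = &ua[3 * m];
        double fx = f * v[0], fy = f * v[1], fz = f * v[2];
        Fi[0] += fx; Fi[1] += fy; Fi[2] += fz;
        Ti[0] += u[1] * fz - u[2] * fy;
        Ti[1] += u[2] * fx - u[0] * fz;
        Ti[2] += u[0] * fy - u[1] * fx;
        Fj[0] -= fx; Fj[1] -= fy; Fj[2] -= fz;
      }
    }
    // P-P: (u_ia + d) - u_jb = va - ub
    double rc2 = pp.rc * pp.rc;
    for (int m = 0; m < nka; m++) {
      const double *v = &va[3 * m];
      const double *ui = &ua[3 * m];
      for (int n = 0; n < nkb; n++) {
        const double *uj = &ub[3 * n];
        double rx = v[0] - uj[0], ry = v[1] - uj[1], rz = v[2] - uj[2];
        double r2 = rx * rx + ry * ry + rz * rz;
        if (r2 < rc2) {
          double f = soft_f(r2, pp.A, pp.rc, energy);
          double fx = f * rx, fy = f * ry, fz = f * rz;
          Fi[0] += fx; Fi[1] += fy; Fi[2] += fz;
          Ti[0] += ui[1] * fz - ui[2] * fy;
          Ti[1] += ui[2] * fx - ui[0] * fz;
          Ti[2] += ui[0] * fy - ui[1] * fx;
          Fj[0] -= fx; Fj[1] -= fy; Fj[2] -= fz;
          Tj[0] -= uj[1] * fz - uj[2] * fy;
          Tj[1] -= uj[2] * fx - uj[0] * fz;
          Tj[2] -= uj[0] * fy - uj[1] * fx;
        }
      }
    }
  }

  // one-sided WCA wall acting on every atom in the wall-normal coordinate
  void plate_forces() {
    double wcutB = std::cbrt(2.0) * pp.sB * pp.sB;  // squared cutoffs
    double wcutP = std::cbrt(2.0) * pp.sP * pp.sP;
    for (int c = 0; c < N; c++) {
      double *Fc = &F[3 * c], *Tc = &T[3 * c];
      // body atom
      double zb = pos[3 * c + 2];
      double dlo = zb - zlo, dhi = zhi - zb;
      if (dlo * dlo < wcutB && dlo > 0) {
        double f = wca_f(dlo * dlo, pp.sB * pp.sB, pp.eps, pp.fcap, energy);
        Fc[2] += f * dlo;
      } else if (dlo <= 0) { Fc[2] += pp.fcap; energy += pp.eps; }
      if (dhi * dhi < wcutB && dhi > 0) {
        double f = wca_f(dhi * dhi, pp.sB * pp.sB, pp.eps, pp.fcap, energy);
        Fc[2] -= f * dhi;
      } else if (dhi <= 0) { Fc[2] -= pp.fcap; energy += pp.eps; }
      // adhesins
      const double *W = &world[(size_t)3 * na * (size_t)c];
      for (int a = 0; a < na; a++) {
        const double *u = &W[3 * a];
        double z = zb + u[2];
        double dl = z - zlo, dh = zhi - z;
        double fz = 0.0;
        if (dl * dl < wcutP && dl > 0)
          fz += wca_f(dl * dl, pp.sP * pp.sP, pp.eps, pp.fcap, energy) * dl;
        else if (dl <= 0) { fz += pp.fcap; energy += pp.eps; }
        if (dh * dh < wcutP && dh > 0)
          fz -= wca_f(dh * dh, pp.sP * pp.sP, pp.eps, pp.fcap, energy) * dh;
        else if (dh <= 0) { fz -= pp.fcap; energy += pp.eps; }
        if (fz != 0.0) {
          Fc[2] += fz;
          Tc[0] += u[1] * fz;
          Tc[1] -= u[0] * fz;
        }
      }
    }
  }

  void forces_neighbor() {
    if (!cand_valid || cand_expired()) {
      build_candidates();
    } else if (!plates_on) {
      for (int c = 0; c < N; c++)
        if (cact[c]) rot_only(c);
    }
    if (plates_on)
      for (int c = 0; c < N; c++) world_coords(c);
    std::fill(F.begin(), F.end(), 0.0);
    std::fill(T.begin(), T.end(), 0.0);
    energy = 0.0;
    for (size_t m = 0; m < cp_i.size(); m++) pair_forces((int)m);
    if (plates_on) plate_forces();
  }

  // all-pairs, all-atoms reference path (no pruning, no pair list)
  void forces_brute() {
    std::fill(F.begin(), F.end(), 0.0);
    std::fill(T.begin(), T.end(), 0.0);
    energy = 0.0;
    for (int c = 0; c < N; c++) world_coords(c);
    double rc2 = pp.rc * pp.rc;
    for (int i = 0; i < N; i++)
      for (int j = i + 1; j < N; j++) {
        double d[3];
        dmin(&pos[3 * i], &pos[3 * j], d);
        const double *Wi = &world[(size_t)3 * na * (size_t)i];
        const double *Wj = &world[(size_t)3 * na * (size_t)j];
        // all atom pairs; atom index 0 = body, 1..na = adhesins
        for (int a = 0; a <= na; a++) {
          double ua[3] = {0, 0, 0};
          if (a > 0) { ua[0] = Wi[3 * (a - 1)]; ua[1] = Wi[3 * (a - 1) + 1]; ua[2] = Wi[3 * (a - 1) + 2]; }
          for (int b = 0; b <= na; b++) {
            double ub[3] = {0, 0, 0};
            if (b > 0) { ub[0] = Wj[3 * (b - 1)]; ub[1] = Wj[3 * (b - 1) + 1]; ub[2] = Wj[3 * (b - 1) + 2]; }
            double v[3] = {ua[0] + d[0] - ub[0], ua[1] + d[1] - ub[1], ua[2] + d[2] - ub[2]};
            double r2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
            double f = 0.0;
            if (a == 0 && b == 0) {
              if (r2 < pp.cut2BB) f = wca_f(r2, pp.s2BB, pp.eps, pp.fcap, energy);
            } else if (a == 0 || b == 0) {
              if (r2 < pp.cut2BP) f = wca_f(r2, pp.s2BP, pp.eps, pp.fcap, energy);
            } else {
              if (r2 < rc2) f = soft_f(r2, pp.A, pp.rc, energy);
            }
            if (f != 0.0) {
              double fx = f * v[0], fy = f * v[1], fz = f * v[2];
              F[3 * i] += fx; F[3 * i + 1] += fy; F[3 * i + 2] += fz;
              F[3 * j] -= fx; F[3 * j + 1] -= fy; F[3 * j + 2] -= fz;
              T[3 * i] += ua[1] * fz - ua[2] * fy;
              T[3 * i + 1] += ua[2] * fx - ua[0] * fz;
              T[3 * i + 2] += ua[0] * fy - ua[1] * fx;
              T[3 * j] -= ub[1] * fz - ub[2] * fy;
              T[3 * j + 1] -= ub[2] * fx - ub[0] * fz;
              T[3 * j + 2] -= ub[0] * fy - ub[1] * fx;
            }
          }
        }
      }
  }

  inline void wrap(int c) {
    // single-step moves are tiny relative to the box, so a branch suffices
    // (with a floor fallback for pathological jumps)
    for (int k = 0; k < (wrap_z ? 3 : 2); k++) {
      double &x = pos[3 * c + k];
      if (x >= box[k]) {
        x -= box[k];
        if (x >= box[k]) {
          if (x > 1e6 * box[k]) lost = true;
          x -= box[k] * std::floor(x / box[k]);
        }
      } else if (x < 0.0) {
        x += box[k];
        if (x < 0.0) {
          if (x < -1e6 * box[k]) lost = true;
          x -= box[k] * std::floor(x / box[k]);
        }
      }
    }
  }

  inline void rotate_quat(int c, double h, bool renorm) {
    double wx = ang[3 * c], wy = ang[3 * c + 1], wz = ang[3 * c + 2];
    double th = std::sqrt(wx * wx + wy * wy + wz * wz) * h;
    rotacc[c] += th;
    double *q = &quat[4 * c];
    if (th < 1e-14) return;
    double sh, ch;
    double half = 0.5 * th;
    if (half < 1e-2) {  // series, |err| < 1e-12
      double h2 = half * half;
      sh = half * (1.0 - h2 / 6.0 * (1.0 - h2 / 20.0));
      ch = 1.0 - h2 / 2.0 * (1.0 - h2 / 12.0);
    } else {
      sh = std::sin(half); ch = std::cos(half);
    }
    double n = sh * h / th;  // sh / |w|
    double dw = ch, dx = wx * n, dy = wy * n, dz = wz * n;
    double qw = q[0], qx = q[1], qy = q[2], qz = q[3];
    q[0] = dw * qw - dx * qx - dy * qy - dz * qz;
    q[1] = dw * qx + dx * qw + dy * qz - dz * qy;
    q[2] = dw * qy - dx * qz + dy * qw + dz * qx;
    q[3] = dw * qz + dx * qy - dy * qx + dz * qw;
    if (renorm) {
      double nn = 1.0 / std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] +
                                  q[3] * q[3]);
      q[0] *= nn; q[1] *= nn; q[2] *= nn; q[3] *= nn;
    }
  }

  double kinetic() const {
    double e = 0.0;
    for (int i = 0; i < 3 * N; i++) {
      e += 0.5 * M * vel[i] * vel[i] + 0.5 * I * ang[i] * ang[i];
    }
    return e;
  }
};

static NumericMatrix to_mat(const std::vector<double> &v, int n, int m) {
  NumericMatrix out(n, m);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < m; k++) out(i, k) = v[m * i + k];
  return out;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix quat, NumericMatrix local,
                NumericVector box, List params, bool wrap_z = true,
                std::string method = "neighbor") {
  int N = pos.nrow();
  NumericMatrix vel(N, 3), angv(N, 3);
  Engine e(pos, quat, vel, angv, local, box, params, 1.0, 1.0, wrap_z);
  if (method == "brute") e.forces_brute(); else e.forces_neighbor();
  return List::create(_["force"] = to_mat(e.F, N, 3),
                      _["torque"] = to_mat(e.T, N, 3),
                      _["energy"] = e.energy);
}

// [[Rcpp::export]]
List cpp_run_phase(NumericMatrix pos, NumericMatrix quat, NumericMatrix vel,
                   NumericMatrix angvel, NumericMatrix local,
                   NumericVector box, List params, int n_steps, double dt,
                   double kBT, double gamma, double mass, double inertia,
                   double seed, int record_every = 0,
                   Nullable<NumericVector> plates = R_NilValue,
                   bool wrap_z = true, int diag_every = 0) {
  Engine e(pos, quat, vel, angvel, local, box, params, mass, inertia, wrap_z);
  Rng rng((uint64_t)seed);
  double h = dt, h2 = 0.5 * dt;
  double h2m = h2 / mass, h2i = h2 / inertia;
  double a = std::exp(-gamma * dt);
  double bT = std::sqrt((1.0 - a * a) * kBT / mass);
  double bR = std::sqrt((1.0 - a * a) * kBT / inertia);
  int N = e.N;

  bool compress = false;
  double zlo0 = 0, zhi0 = 0, zlo1 = 0, zhi1 = 0;
  if (plates.isNotNull()) {
    NumericVector pl(plates);
    compress = true;
    zlo0 = pl[0]; zhi0 = pl[1]; zlo1 = pl[2]; zhi1 = pl[3];
    e.plates_on = true; e.zlo = zlo0; e.zhi = zhi0;
  }

  List snaps;
  std::vector<double> times;
  std::vector<double> diag_t, diag_ke, diag_pe;

  e.forces_neighbor();
  if (diag_every > 0) {
    diag_t.push_back(0.0);
    diag_ke.push_back(e.kinetic());
    diag_pe.push_back(e.energy);
  }

  for (int s = 1; s <= n_steps; s++) {
    // B
    for (int i = 0; i < 3 * N; i++) {
      e.vel[i] += h2m * e.F[i];
      e.ang[i] += h2i * e.T[i];
    }
    // A
    for (int c = 0; c < N; c++) {
      for (int k = 0; k < 3; k++) e.pos[3 * c + k] += h2 * e.vel[3 * c + k];
      e.wrap(c);
      e.rotate_quat(c, h2, false);
    }
    // O
    if (gamma > 0.0) {
      for (int i = 0; i < 3 * N; i++) {
        e.vel[i] = a * e.vel[i] + bT * rng.norm();
        e.ang[i] = a * e.ang[i] + bR * rng.norm();
      }
    }
    // A (renormalize quaternions once per full step)
    for (int c = 0; c < N; c++) {
      for (int k = 0; k < 3; k++) e.pos[3 * c + k] += h2 * e.vel[3 * c + k];
      e.wrap(c);
      e.rotate_quat(c, h2, true);
    }
    // plates schedule (position at end-of-step time)
    if (compress) {
      double fr = (double)s / (double)n_steps;
      e.zlo = zlo0 + fr * (zlo1 - zlo0);
      e.zhi = zhi0 + fr * (zhi1 - zhi0);
    }
    // forces at new positions (pair list / candidate refresh handled inside)
    e.forces_neighbor();
    // B
    for (int i = 0; i < 3 * N; i++) {
      e.vel[i] += h2m * e.F[i];
      e.ang[i] += h2i * e.T[i];
    }

    if (record_every > 0 && s % record_every == 0) {
      snaps.push_back(List::create(
          _["time"] = s * h, _["pos"] = to_mat(e.pos, N, 3),
          _["quat"] = to_mat(e.quat, N, 4), _["vel"] = to_mat(e.vel, N, 3),
          _["angvel"] = to_mat(e.ang, N, 3)));
      times.push_back(s * h);
    }
    if (diag_every > 0 && s % diag_every == 0) {
      diag_t.push_back(s * h);
      diag_ke.push_back(e.kinetic());
      diag_pe.push_back(e.energy);
    }
    if (e.lost)
      stop("integration blow-up: a cell jumped over 1e6 box lengths at step %d",
           s);
    if (s % 1000 == 0 || s == n_steps) {
      for (int i = 0; i < 3 * N; i++)
        if (!std::isfinite(e.pos[i]) || !std::isfinite(e.vel[i]))
          stop("integration blow-up: non-finite state at step %d", s);
      if (s % 20000 == 0) Rcpp::checkUserInterrupt();
    }
  }

  List out = List::create(
      _["pos"] = to_mat(e.pos, N, 3), _["quat"] = to_mat(e.quat, N, 4),
      _["vel"] = to_mat(e.vel, N, 3), _["angvel"] = to_mat(e.ang, N, 3),
      _["snapshots"] = snaps, _["snapshot_times"] = wrap(times),
      _["energy"] = e.energy);
  if (diag_every > 0)
    out["diagnostics"] = DataFrame::create(
        _["time"] = wrap(diag_t), _["kinetic"] = wrap(diag_ke),
        _["potential"] = wrap(diag_pe));
  if (compress) {
    out["plate_lo"] = e.zlo;
    out["plate_hi"] = e.zhi;
  }
  return out;
}
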