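// Compiled core: energy/force evaluation for all interaction terms,
// cell-linked-list neighbor lists with per-term particle subsets, and the
// Langevin velocity-Verlet integrator with counter-based Gaussian noise.
//
// Unit system: Angstrom, fs, amu, kcal/mol.  Forces are kcal/mol/A;
// accelerations use the conversion 4.184e-4 (A/fs^2 per kcal/mol/A/amu).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

static const double ACC = 4.184e-4;   // (kcal/mol/A)/amu -> A/fs^2
static const double KB  = 1.987204e-3; // kcal/mol/K

// ---------------------------------------------------------------- geometry

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v{x, y, z}; return v; }
static inline V3 operator-(V3 a, V3 b) { return v3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator+(V3 a, V3 b) { return v3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator*(double s, V3 a) { return v3(s*a.x, s*a.y, s*a.z); }
static inline V3 operator*(V3 a, double s) { return v3(a.x*s, a.y*s, a.z*s); }
static inline double dot(V3 a, V3 b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(V3 a) { return std::sqrt(dot(a, a)); }

struct Box {
  bool periodic; double L[3];
};

static inline V3 delta(const double* pos, int i, int j, const Box& box) {
  // r_i - r_j with minimum image when periodic
  V3 d = v3(pos[3*i] - pos[3*j], pos[3*i+1] - pos[3*j+1],
            pos[3*i+2] - pos[3*j+2]);
  if (box.periodic) {
    d.x -= box.L[0] * std::nearbyint(d.x / box.L[0]);
    d.y -= box.L[1] * std::nearbyint(d.y / box.L[1]);
    d.z -= box.L[2] * std::nearbyint(d.z / box.L[2]);
  }
  return d;
}

// ------------------------------------------------------------ counter RNG
// Deterministic counter-based stream: the draw for (seed, step, slot) never
// depends on evaluation order, so trajectories are reproducible regardless
// of how work is scheduled.

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unit_open(uint64_t z) {
  // (0, 1): never exactly 0 so log() is safe
  return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double gauss_draw(uint64_t seed, uint64_t step, uint64_t slot) {
  // slots are consumed in pairs: slot 2k and 2k+1 share one Box-Muller draw
  uint64_t base = slot >> 1;
  uint64_t k = mix64(mix64(mix64(seed) ^ step) ^ (0x5851F42D4C957F2DULL + base));
  double u1 = unit_open(mix64(k ^ 0xA0761D6478BD642FULL));
  double u2 = unit_open(mix64(k ^ 0xE7037ED1A0B428DBULL));
  double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
  return (slot & 1ULL) ? r * std::sin(a) : r * std::cos(a);
}

// [[Rcpp::export]]
NumericVector cpp_gauss_stream(double seed, double step, double slot0, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = gauss_draw((uint64_t)seed, (uint64_t)step, (uint64_t)(slot0 + i));
  }
  return out;
}

// ------------------------------------------------------- tabulated splines

struct Table {
  double x0, dx; bool periodic; std::vector<double> E, dE;
  double eval(double x, double* d) const {
    int n = (int)E.size();
    double span = dx * (n - 1);
    if (periodic) {
      double t = (x - x0) / span;
      t -= std::floor(t);
      x = x0 + t * span;
    } else if (x <= x0) { *d = 0; return E[0]; }
    else if (x >= x0 + span) { *d = 0; return E[n-1]; }
    double t = (x - x0) / dx;
    int k = (int)t; if (k > n - 2) k = n - 2;
    double u = t - k;
    // cubic Hermite from node values and derivatives (== the source spline)
    double h00 = (1 + 2*u) * (1-u) * (1-u), h10 = u * (1-u) * (1-u);
    double h01 = u * u * (3 - 2*u),        h11 = u * u * (u - 1);
    double g00 = 6*u*(u-1)/dx, g10 = (1-u)*(1-3*u), g01 = -6*u*(u-1)/dx,
           g11 = u*(3*u-2);
    *d = g00*E[k] + g10*dE[k] + g01*E[k+1] + g11*dE[k+1];
    return h00*E[k] + h10*dE[k]*dx + h01*E[k+1] + h11*dE[k+1]*dx;
  }
};

// ------------------------------------------------- angle/dihedral gradients

// angle i-j-k; theta always set; returns false when the gradient is
// undefined (collinear or zero-length arms) and only the force is skipped
static bool angle_grad(V3 u, V3 v, double* theta, V3* gi, V3* gj, V3* gk) {
  double nu = norm(u), nv = norm(v);
  if (nu < 1e-12 || nv < 1e-12) { *theta = 0; return false; }
  double c = dot(u, v) / (nu * nv);
  if (c > 1) c = 1; if (c < -1) c = -1;
  double s2 = 1 - c * c;
  *theta = std::acos(c);
  if (s2 < 1e-12) return false;
  double s = std::sqrt(s2);
  V3 uh = (1.0/nu) * u, vh = (1.0/nv) * v;
  *gi = (1.0/(nu*s)) * (c * uh - vh);
  *gk = (1.0/(nv*s)) * (c * vh - uh);
  *gj = v3(-(gi->x + gk->x), -(gi->y + gk->y), -(gi->z + gk->z));
  return true;
}

// dihedral i-j-k-l; returns phi and gradients; ok=false when near-collinear
static bool dihedral_grad(V3 b1, V3 b2, V3 b3, double* phi,
                          V3* gi, V3* gj, V3* gk, V3* gl) {
  V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  double nb2 = norm(b2);
  double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
  double b1sq = dot(b1, b1), b3sq = dot(b3, b3), b2sq = nb2 * nb2;
  *phi = std::atan2(dot(cross(n1, n2), (1.0/nb2) * b2), dot(n1, n2));
  // safe fallback: sin^2 of either bending angle below threshold
  if (b1sq * b2sq <= 0 || b3sq * b2sq <= 0) return false;
  if (n1sq / (b1sq * b2sq) < 1e-6 || n2sq / (b3sq * b2sq) < 1e-6) return false;
  V3 ti = (-nb2 / n1sq) * n1;
  V3 tl = ( nb2 / n2sq) * n2;
  double c12 = dot(b1, b2) / b2sq, c32 = dot(b3, b2) / b2sq;
  *gi = ti;
  *gl = tl;
  *gj = (-1.0 - c12) * ti + c32 * tl;
  *gk = c12 * ti + (-1.0 - c32) * tl;
  return true;
}

// modulating gate: f in [0,1], df/d(dtheta)
static inline double gate(double dth, double gamma, double* df) {
  double a = std::fabs(dth);
  if (a < gamma) { *df = 0; return 1.0; }
  if (a >= 2 * gamma) { *df = 0; return 0.0; }
  double c = std::cos(M_PI * dth / (2 * gamma));
  *df = (M_PI / (2 * gamma)) * std::sin(M_PI * dth / gamma);
  return 1.0 - c * c;
}

// Morse split about r0
static inline double morse_rep(double r, double eps, double alpha, double r0,
                               double* d) {
  if (r >= r0) { *d = 0; return 0; }
  double x = std::exp(-alpha * (r - r0));
  *d = 2 * eps * alpha * (1 - x) * x;
  return eps * (1 - x) * (1 - x);
}
static inline double morse_attr(double r, double eps, double alpha, double r0,
                                double* d) {
  if (r < r0) { *d = 0; return -eps; }
  double x = std::exp(-alpha * (r - r0));
  *d = 2 * eps * alpha * (1 - x) * x;
  return eps * (1 - x) * (1 - x) - eps;
}

// ------------------------------------------------------------ system spec

// exclusion lists as per-particle sorted adjacency (few entries each)
struct ExclAdj {
  std::vector<std::vector<int> > adj;
  void init(int n) { adj.assign(n, std::vector<int>()); }
  void add(int i, int j) {
    if (i >= 0 && j >= 0) { adj[i].push_back(j); adj[j].push_back(i); }
  }
  void finish() {
    for (auto& v : adj) { std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end()); }
  }
  bool has(int i, int j) const {
    const std::vector<int>& v = adj[i];
    return std::binary_search(v.begin(), v.end(), j);
  }
};

struct System {
  int n = 0;
  std::vector<double> mass, charge, radius, lambda, sigp, epsp;
  std::vector<int> base;        // 0..3 = A C G T, -1 otherwise

  // bonded records
  std::vector<int> b_i, b_j, b_f;       std::vector<double> b_b0, b_c1, b_c2;
  std::vector<int> a_i, a_j, a_k, a_f, a_t; std::vector<double> a_th0, a_ka;
  std::vector<int> d_i, d_j, d_k, d_l, d_f, d_t;
  std::vector<double> d_phi0, d_mult, d_kd, d_sig;
  std::vector<int> c_i, c_j;            std::vector<double> c_sig, c_eps;
  std::vector<int> g_i, g_k;            std::vector<double> g_r0, g_eps, g_w;

  // DNA / protein-DNA site records
  std::vector<int> st_i, st_j, st_s;
  std::vector<double> st_eps, st_al, st_r0, st_th0, st_g;
  std::vector<int> bp_i, bp_j, bp_si, bp_sj;
  std::vector<double> bp_eps, bp_al, bp_r0, bp_t10, bp_t20, bp_p0, bp_g;
  std::vector<int> cs_i, cs_j, cs_ai, cs_aj;
  std::vector<double> cs_eps, cs_al, cs_r0, cs_t30, cs_tc0, cs_g;
  std::vector<int> pw_j, pw_jm, pw_jp;
  std::vector<double> pw_r0, pw_t10, pw_t20, pw_t30, pw_g, pw_w;
  std::vector<double> pw_eps;           // 4 per record: effective eps by base
  std::vector<int> hb_i, hb_j, hb_si, hb_j2;
  std::vector<double> hb_r0, hb_t10, hb_t20, hb_g, hb_eps, hb_w;
  // sugar and 5' base adjacent to each base particle (for pwmcos angles)
  std::vector<int> base_sugar, base_prev;

  std::vector<Table> tables;

  // generic nonbonded control
  bool use_exv = false, use_hps = false, use_ele = false, use_pwm = false;
  double eps_exv = 0.6;
  double eps_r = 80.0, lambda_D = 1e30, kc_over_epsr = 0.0;
  double rc_ele = 52, rp_ele = 57, rc_hps = 39, rp_hps = 44;
  double rc_bp = 18, rp_bp = 23, rp_exv = 15, rp_pwm = 23;
  std::vector<int> exv_set, hps_set, ele_set, pwm_bases;  // subset members
  ExclAdj excl_common, excl_exv;
};

static std::vector<double> numvec(List L, const char* nm) {
  return as<std::vector<double> >(L[nm]);
}
static std::vector<int> intvec(List L, const char* nm) {
  return as<std::vector<int> >(L[nm]);
}

static System parse_system(List S) {
  System s;
  s.n = as<int>(S["n"]);
  s.mass = numvec(S, "mass"); s.charge = numvec(S, "charge");
  s.radius = numvec(S, "radius"); s.lambda = numvec(S, "lambda");
  s.sigp = numvec(S, "sigma"); s.epsp = numvec(S, "eps");
  s.base = intvec(S, "base");

  List b = S["bonds"];
  s.b_i = intvec(b, "i"); s.b_j = intvec(b, "j"); s.b_f = intvec(b, "func");
  s.b_b0 = numvec(b, "b0"); s.b_c1 = numvec(b, "c1"); s.b_c2 = numvec(b, "c2");
  List a = S["angles"];
  s.a_i = intvec(a, "i"); s.a_j = intvec(a, "j"); s.a_k = intvec(a, "k");
  s.a_f = intvec(a, "func"); s.a_t = intvec(a, "table");
  s.a_th0 = numvec(a, "theta0"); s.a_ka = numvec(a, "ka");
  List d = S["dihedrals"];
  s.d_i = intvec(d, "i"); s.d_j = intvec(d, "j"); s.d_k = intvec(d, "k");
  s.d_l = intvec(d, "l"); s.d_f = intvec(d, "func"); s.d_t = intvec(d, "table");
  s.d_phi0 = numvec(d, "phi0"); s.d_mult = numvec(d, "mult");
  s.d_kd = numvec(d, "kd"); s.d_sig = numvec(d, "sigma");
  List cc = S["contacts"];
  s.c_i = intvec(cc, "i"); s.c_j = intvec(cc, "j");
  s.c_sig = numvec(cc, "sigma"); s.c_eps = numvec(cc, "eps");
  List g = S["gauss13"];
  s.g_i = intvec(g, "i"); s.g_k = intvec(g, "k");
  s.g_r0 = numvec(g, "r0"); s.g_eps = numvec(g, "eps"); s.g_w = numvec(g, "w");

  List st = S["stacks"];
  s.st_i = intvec(st, "i"); s.st_j = intvec(st, "j"); s.st_s = intvec(st, "s");
  s.st_eps = numvec(st, "eps"); s.st_al = numvec(st, "alpha");
  s.st_r0 = numvec(st, "r0"); s.st_th0 = numvec(st, "theta0");
  s.st_g = numvec(st, "gamma");
  List bp = S["basepairs"];
  s.bp_i = intvec(bp, "i"); s.bp_j = intvec(bp, "j");
  s.bp_si = intvec(bp, "si"); s.bp_sj = intvec(bp, "sj");
  s.bp_eps = numvec(bp, "eps"); s.bp_al = numvec(bp, "alpha");
  s.bp_r0 = numvec(bp, "r0"); s.bp_t10 = numvec(bp, "theta1_0");
  s.bp_t20 = numvec(bp, "theta2_0"); s.bp_p0 = numvec(bp, "phi0");
  s.bp_g = numvec(bp, "gamma");
  List cs = S["crossstacks"];
  s.cs_i = intvec(cs, "i"); s.cs_j = intvec(cs, "j");
  s.cs_ai = intvec(cs, "ai"); s.cs_aj = intvec(cs, "aj");
  s.cs_eps = numvec(cs, "eps"); s.cs_al = numvec(cs, "alpha");
  s.cs_r0 = numvec(cs, "r0"); s.cs_t30 = numvec(cs, "theta3_0");
  s.cs_tc0 = numvec(cs, "thetaCS_0"); s.cs_g = numvec(cs, "gamma");
  List pw = S["pwmcos"];
  s.pw_j = intvec(pw, "j"); s.pw_jm = intvec(pw, "jm");
  s.pw_jp = intvec(pw, "jp"); s.pw_r0 = numvec(pw, "r0");
  s.pw_t10 = numvec(pw, "theta1_0"); s.pw_t20 = numvec(pw, "theta2_0");
  s.pw_t30 = numvec(pw, "theta3_0"); s.pw_g = numvec(pw, "gamma");
  s.pw_w = numvec(pw, "w"); s.pw_eps = numvec(pw, "eps_by_base");
  List hb = S["hb"];
  s.hb_i = intvec(hb, "i"); s.hb_j = intvec(hb, "j");
  s.hb_si = intvec(hb, "si"); s.hb_j2 = intvec(hb, "j2");
  s.hb_r0 = numvec(hb, "r0"); s.hb_t10 = numvec(hb, "theta1_0");
  s.hb_t20 = numvec(hb, "theta2_0"); s.hb_g = numvec(hb, "gamma");
  s.hb_eps = numvec(hb, "eps"); s.hb_w = numvec(hb, "w");
  s.base_sugar = intvec(S, "base_sugar");
  s.base_prev = intvec(S, "base_prev");

  List tabs = S["tables"];
  for (int t = 0; t < tabs.size(); ++t) {
    List tl = tabs[t];
    Table tb;
    tb.x0 = as<double>(tl["x0"]); tb.dx = as<double>(tl["dx"]);
    tb.periodic = as<int>(tl["periodic"]) != 0;
    tb.E = as<std::vector<double> >(tl["E"]);
    tb.dE = as<std::vector<double> >(tl["dE"]);
    s.tables.push_back(tb);
  }

  List nb = S["nonbonded"];
  s.use_exv = as<bool>(nb["use_exv"]); s.use_hps = as<bool>(nb["use_hps"]);
  s.use_ele = as<bool>(nb["use_ele"]); s.use_pwm = as<bool>(nb["use_pwm"]);
  s.eps_exv = as<double>(nb["eps_exv"]);
  s.eps_r = as<double>(nb["eps_r"]); s.lambda_D = as<double>(nb["lambda_D"]);
  s.kc_over_epsr = 332.0637 / s.eps_r;
  s.rc_ele = as<double>(nb["rc_ele"]); s.rp_ele = as<double>(nb["rp_ele"]);
  s.rc_hps = as<double>(nb["rc_hps"]); s.rp_hps = as<double>(nb["rp_hps"]);
  s.rc_bp = as<double>(nb["rc_bp"]); s.rp_bp = as<double>(nb["rp_bp"]);
  s.rp_exv = as<double>(nb["rp_exv"]); s.rp_pwm = as<double>(nb["rp_pwm"]);
  s.exv_set = intvec(nb, "exv_set"); s.hps_set = intvec(nb, "hps_set");
  s.ele_set = intvec(nb, "ele_set"); s.pwm_bases = intvec(nb, "pwm_bases");

  s.excl_common.init(s.n); s.excl_exv.init(s.n);
  IntegerMatrix exc = S["excl_common"];
  for (int r = 0; r < exc.nrow(); ++r) {
    s.excl_common.add(exc(r, 0), exc(r, 1));
  }
  IntegerMatrix exv = S["excl_exv"];
  for (int r = 0; r < exv.nrow(); ++r) {
    s.excl_exv.add(exv(r, 0), exv(r, 1));
  }
  s.excl_common.finish(); s.excl_exv.finish();
  return s;
}

// -------------------------------------------------------------- cell lists

struct CellGrid {
  Box box; int nc[3]; double edge[3]; double origin[3];
  std::vector<std::vector<int> > heads;  // particle ids per cell (one subset)
};

// Build pair candidates for one subset (or cross subsets A x B) within rP.
static void cell_pairs(const double* pos, int npart, const Box& box,
                       const std::vector<int>& setA,
                       const std::vector<int>& setB, bool cross,
                       double rP, const ExclAdj* excl,
                       std::vector<int>& out_i, std::vector<int>& out_j) {
  double lo[3] = {0, 0, 0}, L[3];
  if (box.periodic) {
    for (int d = 0; d < 3; ++d) L[d] = box.L[d];
  } else {
    double hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = 1e300; hi[d] = -1e300; }
    auto scan = [&](const std::vector<int>& S) {
      for (int idx : S) for (int d = 0; d < 3; ++d) {
        double c = pos[3*idx + d];
        if (c < lo[d]) lo[d] = c;
        if (c > hi[d]) hi[d] = c;
      }
    };
    scan(setA); if (cross) scan(setB);
    for (int d = 0; d < 3; ++d) {
      lo[d] -= 0.5; L[d] = (hi[d] - lo[d]) + 1.0;
      if (L[d] < 1.0) L[d] = 1.0;
    }
  }
  int nc[3]; double edge[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor(L[d] / rP));
    if (!box.periodic) nc[d] = std::max(1, (int)std::floor(L[d] / rP));
    edge[d] = L[d] / nc[d];
  }
  auto cell_of = [&](int idx) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      double x = pos[3*idx + d] - lo[d];
      if (box.periodic) x = x - L[d] * std::floor(x / L[d]);
      c[d] = std::min(nc[d] - 1, std::max(0, (int)(x / edge[d])));
    }
    return (c[0] * nc[1] + c[1]) * nc[2] + c[2];
  };
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int> > cellsA(ncell), cellsB;
  for (int idx : setA) cellsA[cell_of(idx)].push_back(idx);
  if (cross) { cellsB.resize(ncell); for (int idx : setB) cellsB[cell_of(idx)].push_back(idx); }

  // neighboring-cell offsets by the minimum inter-cell distance criterion
  int kr[3];
  for (int d = 0; d < 3; ++d) {
    kr[d] = (int)std::floor(rP / edge[d]) + 1;
    if (box.periodic) kr[d] = std::min(kr[d], (nc[d] - 1) / 2);
    else kr[d] = std::min(kr[d], nc[d] - 1);
  }
  std::vector<std::array<int,3> > offs;
  for (int dx = -kr[0]; dx <= kr[0]; ++dx)
  for (int dy = -kr[1]; dy <= kr[1]; ++dy)
  for (int dz = -kr[2]; dz <= kr[2]; ++dz) {
    if (dx == 0 && dy == 0 && dz == 0) continue;
    double rmin2 = 0; int dd[3] = {dx, dy, dz};
    for (int d = 0; d < 3; ++d) {
      int ad = std::abs(dd[d]);
      if (ad > 0) { double m = (ad - 1) * edge[d]; rmin2 += m * m; }
    }
    if (rmin2 >= rP * rP) continue;
    if (!cross) {
      // enumerate each unordered cell pair once
      if (dx < 0 || (dx == 0 && (dy < 0 || (dy == 0 && dz < 0)))) continue;
    }
    offs.push_back({dx, dy, dz});
  }
  double rP2 = rP * rP;
  auto check_pair = [&](int a, int b) {
    if (!cross && a == b) return;
    V3 dv = delta(pos, a, b, box);
    if (dot(dv, dv) >= rP2) return;
    if (excl && excl->has(a, b)) return;
    int i = a, j = b;
    if (!cross && i > j) std::swap(i, j);
    out_i.push_back(i); out_j.push_back(j);
  };
  for (int cx = 0; cx < nc[0]; ++cx)
  for (int cy = 0; cy < nc[1]; ++cy)
  for (int cz = 0; cz < nc[2]; ++cz) {
    int ci = (cx * nc[1] + cy) * nc[2] + cz;
    const std::vector<int>& A = cellsA[ci];
    if (A.empty() && !cross) continue;
    // same cell
    if (!cross) {
      for (size_t p = 0; p < A.size(); ++p)
        for (size_t q = p + 1; q < A.size(); ++q) check_pair(A[p], A[q]);
    } else {
      const std::vector<int>& B0 = cellsB[ci];
      for (int a : A) for (int b : B0) check_pair(a, b);
    }
    for (const auto& o : offs) {
      int ox = cx + o[0], oy = cy + o[1], oz = cz + o[2];
      if (box.periodic) {
        ox = (ox % nc[0] + nc[0]) % nc[0];
        oy = (oy % nc[1] + nc[1]) % nc[1];
        oz = (oz % nc[2] + nc[2]) % nc[2];
      } else if (ox < 0 || oy < 0 || oz < 0 ||
                 ox >= nc[0] || oy >= nc[1] || oz >= nc[2]) continue;
      int ck = (ox * nc[1] + oy) * nc[2] + oz;
      const std::vector<int>& B = cross ? cellsB[ck] : cellsA[ck];
      for (int a : A) for (int b : B) check_pair(a, b);
    }
  }
}

// [[Rcpp::export]]
List cpp_build_pairs(NumericMatrix pos, NumericVector boxv, bool periodic,
                     IntegerVector setA, IntegerVector setB, bool cross,
                     double rP, IntegerMatrix excl) {
  int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i) {
    p[3*i] = pos(i, 0); p[3*i+1] = pos(i, 1); p[3*i+2] = pos(i, 2);
  }
  Box box; box.periodic = periodic;
  if (periodic) for (int d = 0; d < 3; ++d) box.L[d] = boxv[d];
  ExclAdj ex; ex.init(n);
  for (int r = 0; r < excl.nrow(); ++r) ex.add(excl(r,0), excl(r,1));
  ex.finish();
  std::vector<int> A = as<std::vector<int> >(setA);
  std::vector<int> B = as<std::vector<int> >(setB);
  std::vector<int> oi, oj;
  cell_pairs(p.data(), n, box, A, B, cross, rP, excl.nrow() ? &ex : nullptr,
             oi, oj);
  IntegerMatrix out(oi.size(), 2);
  for (size_t r = 0; r < oi.size(); ++r) { out(r,0) = oi[r]; out(r,1) = oj[r]; }
  return List::create(_["pairs"] = out);
}

// ------------------------------------------------------------ force engine

struct Pairs {
  std::vector<int> exv_i, exv_j, hps_i, hps_j, ele_i, ele_j, pw_s, pw_b;
};

enum { T_BOND, T_ANGLE, T_DIHE, T_G13, T_GO, T_EXV, T_ELE, T_HPS,
       T_BSTK, T_BP, T_CSTK, T_PWM, T_HB, NTERM };

static void add_force(std::vector<double>& f, int i, V3 g) {
  f[3*i] += g.x; f[3*i+1] += g.y; f[3*i+2] += g.z;
}

// radial pair helper: given dE/dr, accumulate -dE/dr * rhat on i (and + on j)
static inline void radial(std::vector<double>& f, int i, int j, V3 d,
                          double r, double dEdr) {
  double s = -dEdr / r;
  f[3*i] += s * d.x; f[3*i+1] += s * d.y; f[3*i+2] += s * d.z;
  f[3*j] -= s * d.x; f[3*j+1] -= s * d.y; f[3*j+2] -= s * d.z;
}

static void eval_all(const System& s, const double* pos, const Box& box,
                     const Pairs& pr, double* E, std::vector<double>& f) {
  for (int t = 0; t < NTERM; ++t) E[t] = 0;
  std::fill(f.begin(), f.end(), 0.0);

  // ---- bonds
  for (size_t r = 0; r < s.b_i.size(); ++r) {
    int i = s.b_i[r], j = s.b_j[r];
    V3 d = delta(pos, i, j, box);
    double b = norm(d), db = b - s.b_b0[r], e, de;
    if (s.b_f[r] == 1) { e = s.b_c1[r]*db*db; de = 2*s.b_c1[r]*db; }
    else { e = s.b_c1[r]*db*db + s.b_c2[r]*db*db*db*db;
           de = 2*s.b_c1[r]*db + 4*s.b_c2[r]*db*db*db; }
    E[T_BOND] += e; radial(f, i, j, d, b, de);
  }
  // ---- angles
  for (size_t r = 0; r < s.a_i.size(); ++r) {
    int i = s.a_i[r], j = s.a_j[r], k = s.a_k[r];
    V3 u = delta(pos, i, j, box), v = delta(pos, k, j, box);
    double th; V3 gi, gj, gk;
    bool ok = angle_grad(u, v, &th, &gi, &gj, &gk);
    double e, de;
    if (s.a_f[r] == 1) {
      double dth = th - s.a_th0[r];
      e = s.a_ka[r]*dth*dth; de = 2*s.a_ka[r]*dth;
    } else {
      e = s.tables[s.a_t[r]].eval(th, &de);
    }
    E[T_ANGLE] += e;
    if (ok) {
      add_force(f, i, (-de) * gi); add_force(f, j, (-de) * gj);
      add_force(f, k, (-de) * gk);
    }
  }
  // ---- dihedrals
  for (size_t r = 0; r < s.d_i.size(); ++r) {
    int i = s.d_i[r], j = s.d_j[r], k = s.d_k[r], l = s.d_l[r];
    V3 b1 = delta(pos, j, i, box), b2 = delta(pos, k, j, box),
       b3 = delta(pos, l, k, box);
    double phi; V3 gi, gj, gk, gl;
    bool ok = dihedral_grad(b1, b2, b3, &phi, &gi, &gj, &gk, &gl);
    double e = 0, de = 0;
    int fn = s.d_f[r];
    if (fn == 1 || fn == 32) {
      double dphi = phi - s.d_phi0[r];
      dphi -= 2*M_PI*std::floor((dphi + M_PI)/(2*M_PI));
      e = s.d_kd[r]*(1 + std::cos(s.d_mult[r]*dphi));
      de = -s.d_kd[r]*s.d_mult[r]*std::sin(s.d_mult[r]*dphi);
    } else if (fn == 21) {
      double dphi = phi - s.d_phi0[r];
      dphi -= 2*M_PI*std::floor((dphi + M_PI)/(2*M_PI));
      double g = std::exp(-dphi*dphi/(2*s.d_sig[r]*s.d_sig[r]));
      e = -s.d_kd[r]*g; de = s.d_kd[r]*g*dphi/(s.d_sig[r]*s.d_sig[r]);
    } else { // 22 tabulated
      e = s.tables[s.d_t[r]].eval(phi, &de);
    }
    E[T_DIHE] += e;
    if (ok) {
      add_force(f, i, (-de) * gi); add_force(f, j, (-de) * gj);
      add_force(f, k, (-de) * gk); add_force(f, l, (-de) * gl);
    }
  }
  // ---- 1-3 Gaussians
  for (size_t r = 0; r < s.g_i.size(); ++r) {
    int i = s.g_i[r], k = s.g_k[r];
    V3 d = delta(pos, i, k, box);
    double rr = norm(d), dd = rr - s.g_r0[r];
    double g = std::exp(-dd*dd/(2*s.g_w[r]*s.g_w[r]));
    E[T_G13] += -s.g_eps[r]*g;
    radial(f, i, k, d, rr, s.g_eps[r]*g*dd/(s.g_w[r]*s.g_w[r]));
  }
  // ---- native contacts (no cutoff: pre-defined pairs)
  for (size_t r = 0; r < s.c_i.size(); ++r) {
    int i = s.c_i[r], j = s.c_j[r];
    V3 d = delta(pos, i, j, box);
    double rr = norm(d), x = s.c_sig[r]/rr;
    double x2=x*x, x4=x2*x2, x10=x4*x4*x2, x12=x10*x2;
    E[T_GO] += s.c_eps[r]*(5*x12 - 6*x10);
    radial(f, i, j, d, rr, s.c_eps[r]*(-60*x12 + 60*x10)/rr);
  }
  // ---- generic nonbonded via neighbor lists
  if (s.use_exv) {
    for (size_t r = 0; r < pr.exv_i.size(); ++r) {
      int i = pr.exv_i[r], j = pr.exv_j[r];
      V3 d = delta(pos, i, j, box);
      double r2 = dot(d, d);
      double sg = 0.5*(s.radius[i] + s.radius[j]);
      if (r2 >= 4*sg*sg) continue;
      double x2 = sg*sg/r2, x6 = x2*x2*x2, x12 = x6*x6;
      E[T_EXV] += s.eps_exv*x12 - s.eps_exv/4096.0;
      double g = 12*s.eps_exv*x12/r2;       // -(dE/dr)/r
      f[3*i] += g*d.x; f[3*i+1] += g*d.y; f[3*i+2] += g*d.z;
      f[3*j] -= g*d.x; f[3*j+1] -= g*d.y; f[3*j+2] -= g*d.z;
    }
  }
  if (s.use_hps) {
    const double rc2 = s.rc_hps*s.rc_hps;
    const double CBRT2 = 1.2599210498948732;
    const int np = (int)pr.hps_i.size();
    const int* pi = pr.hps_i.data();
    const int* pj = pr.hps_j.data();
    for (int r = 0; r < np; ++r) {
      int i = pi[r], j = pj[r];
      V3 d = delta(pos, i, j, box);
      double r2 = dot(d, d);
      if (r2 >= rc2) continue;
      double sg = 0.5*(s.sigp[i] + s.sigp[j]);
      double x2 = sg*sg/r2, x6 = x2*x2*x2, x12 = x6*x6;
      double ep = 0.5*(s.epsp[i] + s.epsp[j]);
      double elj = 4*ep*(x12 - x6);
      double g = 4*ep*(12*x12 - 6*x6)/r2;   // -(dE/dr)/r for plain LJ
      if (r2 <= CBRT2*sg*sg) {
        double lm = 0.5*(s.lambda[i] + s.lambda[j]);
        E[T_HPS] += elj + (1 - lm)*ep;
      } else {
        double lm = 0.5*(s.lambda[i] + s.lambda[j]);
        E[T_HPS] += lm*elj;
        g *= lm;
      }
      f[3*i] += g*d.x; f[3*i+1] += g*d.y; f[3*i+2] += g*d.z;
      f[3*j] -= g*d.x; f[3*j+1] -= g*d.y; f[3*j+2] -= g*d.z;
    }
  }
  if (s.use_ele) {
    double rc2 = s.rc_ele*s.rc_ele;
    for (size_t r = 0; r < pr.ele_i.size(); ++r) {
      int i = pr.ele_i[r], j = pr.ele_j[r];
      V3 d = delta(pos, i, j, box);
      double r2 = dot(d, d);
      if (r2 >= rc2) continue;
      double rr = std::sqrt(r2);
      double pre = s.kc_over_epsr * s.charge[i] * s.charge[j];
      double ex = std::exp(-rr/s.lambda_D);
      double e = pre*ex/rr;
      E[T_ELE] += e;
      radial(f, i, j, d, rr, -e*(1/rr + 1/s.lambda_D));
    }
  }
  // ---- base stacking: Morse-rep + f(dtheta) * Morse-attr, no cutoff
  for (size_t r = 0; r < s.st_i.size(); ++r) {
    int i = s.st_i[r], j = s.st_j[r], ss = s.st_s[r];
    V3 d = delta(pos, i, j, box);
    double rr = norm(d), dr, da;
    double erep = morse_rep(rr, s.st_eps[r], s.st_al[r], s.st_r0[r], &dr);
    double eatt = morse_attr(rr, s.st_eps[r], s.st_al[r], s.st_r0[r], &da);
    V3 u = delta(pos, ss, i, box), v = delta(pos, j, i, box);
    double th; V3 gs, gi, gj;
    bool ok = angle_grad(u, v, &th, &gs, &gi, &gj);
    double df, fg = gate(th - s.st_th0[r], s.st_g[r], &df);
    E[T_BSTK] += erep + fg*eatt;
    radial(f, i, j, d, rr, dr + fg*da);
    if (ok && df != 0) {
      double c = -eatt*df;
      add_force(f, ss, c*gs); add_force(f, i, c*gi); add_force(f, j, c*gj);
    }
  }
  // ---- base pairing (cutoff rc_bp)
  for (size_t r = 0; r < s.bp_i.size(); ++r) {
    int i = s.bp_i[r], j = s.bp_j[r], si = s.bp_si[r], sj = s.bp_sj[r];
    V3 d = delta(pos, i, j, box);
    double rr = norm(d);
    if (rr >= s.rc_bp) continue;
    double dr, da;
    double erep = morse_rep(rr, s.bp_eps[r], s.bp_al[r], s.bp_r0[r], &dr);
    double eatt = morse_attr(rr, s.bp_eps[r], s.bp_al[r], s.bp_r0[r], &da);
    // theta1: si-i-j, theta2: i-j-sj, dihedral si-i-j-sj
    double th1, th2, phi;
    V3 a_gi, a_gj, a_gk, t2_gi, t2_gj, t2_gk, p_gi, p_gj, p_gk, p_gl;
    bool ok1 = angle_grad(delta(pos, si, i, box), delta(pos, j, i, box),
                          &th1, &a_gi, &a_gj, &a_gk);
    bool ok2 = angle_grad(delta(pos, i, j, box), delta(pos, sj, j, box),
                          &th2, &t2_gi, &t2_gj, &t2_gk);
    V3 b1 = delta(pos, i, si, box), b2 = delta(pos, j, i, box),
       b3 = delta(pos, sj, j, box);
    bool okp = dihedral_grad(b1, b2, b3, &phi, &p_gi, &p_gj, &p_gk, &p_gl);
    double df1, f1 = gate(th1 - s.bp_t10[r], s.bp_g[r], &df1);
    double df2, f2 = gate(th2 - s.bp_t20[r], s.bp_g[r], &df2);
    double dphi = phi - s.bp_p0[r];
    dphi -= 2*M_PI*std::floor((dphi + M_PI)/(2*M_PI));
    double gphi = 0.5*(1 + std::cos(dphi));
    double dgphi = -0.5*std::sin(dphi);
    double e = erep + gphi*f1*f2*eatt;
    E[T_BP] += e;
    radial(f, i, j, d, rr, dr + gphi*f1*f2*da);
    if (ok1 && df1 != 0) {
      double c = -eatt*gphi*f2*df1;
      add_force(f, si, c*a_gi); add_force(f, i, c*a_gj); add_force(f, j, c*a_gk);
    }
    if (ok2 && df2 != 0) {
      double c = -eatt*gphi*f1*df2;
      add_force(f, i, c*t2_gi); add_force(f, j, c*t2_gj); add_force(f, sj, c*t2_gk);
    }
    if (okp && dgphi != 0) {
      double c = -eatt*f1*f2*dgphi;
      add_force(f, si, c*p_gi); add_force(f, i, c*p_gj);
      add_force(f, j, c*p_gk); add_force(f, sj, c*p_gl);
    }
  }
  // ---- cross stacking (shares the bp cutoff)
  for (size_t r = 0; r < s.cs_i.size(); ++r) {
    int i = s.cs_i[r], j = s.cs_j[r], ai = s.cs_ai[r], aj = s.cs_aj[r];
    V3 d = delta(pos, i, j, box);
    double rr = norm(d);
    if (rr >= s.rc_bp) continue;
    double da;
    double eatt = morse_attr(rr, s.cs_eps[r], s.cs_al[r], s.cs_r0[r], &da);
    double th3, thc;
    V3 g3a, g3b, g3c, gca, gcb, gcc;
    bool ok3 = angle_grad(delta(pos, ai, i, box), delta(pos, j, i, box),
                          &th3, &g3a, &g3b, &g3c);
    bool okc = angle_grad(delta(pos, i, j, box), delta(pos, aj, j, box),
                          &thc, &gca, &gcb, &gcc);
    double df3, f3 = gate(th3 - s.cs_t30[r], s.cs_g[r], &df3);
    double dfc, fc = gate(thc - s.cs_tc0[r], s.cs_g[r], &dfc);
    E[T_CSTK] += f3*fc*eatt;
    radial(f, i, j, d, rr, f3*fc*da);
    if (ok3 && df3 != 0) {
      double c = -eatt*fc*df3;
      add_force(f, ai, c*g3a); add_force(f, i, c*g3b); add_force(f, j, c*g3c);
    }
    if (okc && dfc != 0) {
      double c = -eatt*f3*dfc;
      add_force(f, i, c*gca); add_force(f, j, c*gcb); add_force(f, aj, c*gcc);
    }
  }
  // ---- PWMcos sites x candidate bases
  if (s.use_pwm) {
    for (size_t r = 0; r < pr.pw_s.size(); ++r) {
      int rec = pr.pw_s[r], ib = pr.pw_b[r];
      int j = s.pw_j[rec], jm = s.pw_jm[rec], jp = s.pw_jp[rec];
      int sb = s.base_sugar[ib], pb = s.base_prev[ib];
      if (sb < 0 || pb < 0) continue;
      int bt = s.base[ib];
      if (bt < 0) continue;
      double eps = s.pw_eps[4*rec + bt];
      if (eps == 0) continue;
      V3 d = delta(pos, ib, j, box);
      double rr = norm(d);
      if (rr >= s.pw_r0[rec] + 5.0) continue;
      double dd = rr - s.pw_r0[rec];
      double w = s.pw_w[rec];
      double g = std::exp(-dd*dd/(2*w*w));
      double egauss = -eps*g, dgauss = eps*g*dd/(w*w);
      // theta1: S(i)-B(i)-Ca(j); theta2: B(i)-Ca(j)-Ca(jm);
      // theta3: B5'(i)-B(i)-Ca(j)
      double th1, th2, th3;
      V3 a1, b1v, c1, a2, b2v, c2, a3, b3v, c3;
      bool ok1 = angle_grad(delta(pos, sb, ib, box), delta(pos, j, ib, box),
                            &th1, &a1, &b1v, &c1);
      bool ok2 = angle_grad(delta(pos, ib, j, box), delta(pos, jm, j, box),
                            &th2, &a2, &b2v, &c2);
      bool ok3 = angle_grad(delta(pos, pb, ib, box), delta(pos, j, ib, box),
                            &th3, &a3, &b3v, &c3);
      double df1, f1 = gate(th1 - s.pw_t10[rec], s.pw_g[rec], &df1);
      double df2, f2 = gate(th2 - s.pw_t20[rec], s.pw_g[rec], &df2);
      double df3, f3 = gate(th3 - s.pw_t30[rec], s.pw_g[rec], &df3);
      double fall = f1*f2*f3;
      if (fall == 0 && df1 == 0 && df2 == 0 && df3 == 0) continue;
      E[T_PWM] += egauss*fall;
      radial(f, ib, j, d, rr, dgauss*fall);
      if (ok1 && df1 != 0) {
        double c = -egauss*df1*f2*f3;
        add_force(f, sb, c*a1); add_force(f, ib, c*b1v); add_force(f, j, c*c1);
      }
      if (ok2 && df2 != 0) {
        double c = -egauss*df2*f1*f3;
        add_force(f, ib, c*a2); add_force(f, j, c*b2v); add_force(f, jm, c*c2);
      }
      if (ok3 && df3 != 0) {
        double c = -egauss*df3*f1*f2;
        add_force(f, pb, c*a3); add_force(f, ib, c*b3v); add_force(f, j, c*c3);
      }
      (void)jp;
    }
  }
  // ---- backbone hydrogen-bond sites (fixed pairs, cutoff r0 + 5 A)
  for (size_t r = 0; r < s.hb_i.size(); ++r) {
    int ip = s.hb_i[r], j = s.hb_j[r], si = s.hb_si[r], j2 = s.hb_j2[r];
    V3 d = delta(pos, ip, j, box);
    double rr = norm(d);
    if (rr >= s.hb_r0[r] + 5.0) continue;
    double dd = rr - s.hb_r0[r], w = s.hb_w[r];
    double g = std::exp(-dd*dd/(2*w*w));
    double eg = -s.hb_eps[r]*g, dg = s.hb_eps[r]*g*dd/(w*w);
    double th1, th2;
    V3 a1, b1v, c1, a2, b2v, c2;
    bool ok1 = angle_grad(delta(pos, si, ip, box), delta(pos, j, ip, box),
                          &th1, &a1, &b1v, &c1);
    bool ok2 = angle_grad(delta(pos, ip, j, box), delta(pos, j2, j, box),
                          &th2, &a2, &b2v, &c2);
    double df1, f1 = gate(th1 - s.hb_t10[r], s.hb_g[r], &df1);
    double df2, f2 = gate(th2 - s.hb_t20[r], s.hb_g[r], &df2);
    E[T_HB] += eg*f1*f2;
    radial(f, ip, j, d, rr, dg*f1*f2);
    if (ok1 && df1 != 0) {
      double c = -eg*df1*f2;
      add_force(f, si, c*a1); add_force(f, ip, c*b1v); add_force(f, j, c*c1);
    }
    if (ok2 && df2 != 0) {
      double c = -eg*df2*f1;
      add_force(f, ip, c*a2); add_force(f, j, c*b2v); add_force(f, j2, c*c2);
    }
  }
}

static void build_all_pairs(const System& s, const double* pos,
                            const Box& box, Pairs& pr) {
  pr = Pairs();
  if (s.use_exv) {
    cell_pairs(pos, s.n, box, s.exv_set, s.exv_set, false, s.rp_exv,
               &s.excl_exv, pr.exv_i, pr.exv_j);
  }
  if (s.use_hps) {
    cell_pairs(pos, s.n, box, s.hps_set, s.hps_set, false, s.rp_hps,
               &s.excl_common, pr.hps_i, pr.hps_j);
  }
  if (s.use_ele) {
    cell_pairs(pos, s.n, box, s.ele_set, s.ele_set, false, s.rp_ele,
               &s.excl_common, pr.ele_i, pr.ele_j);
  }
  if (s.use_pwm && s.pw_j.size() > 0) {
    // cross list: site C-alphas x candidate bases; map back to records
    std::vector<int> sites(s.pw_j.size());
    std::vector<std::vector<int> > rec_of(s.n);
    for (size_t r = 0; r < s.pw_j.size(); ++r) {
      sites[r] = s.pw_j[r];
      rec_of[s.pw_j[r]].push_back((int)r);
    }
    std::sort(sites.begin(), sites.end());
    sites.erase(std::unique(sites.begin(), sites.end()), sites.end());
    std::vector<int> ci, cj;
    cell_pairs(pos, s.n, box, sites, s.pwm_bases, true, s.rp_pwm, nullptr,
               ci, cj);
    for (size_t r = 0; r < ci.size(); ++r) {
      for (int rec : rec_of[ci[r]]) {
        pr.pw_s.push_back(rec); pr.pw_b.push_back(cj[r]);
      }
    }
  }
}

static Box parse_box(NumericVector boxv, bool periodic) {
  Box box; box.periodic = periodic;
  if (periodic) for (int d = 0; d < 3; ++d) box.L[d] = boxv[d];
  return box;
}

// [[Rcpp::export]]
List cpp_energy_forces(List sysList, NumericMatrix pos, NumericVector boxv,
                       bool periodic) {
  System s = parse_system(sysList);
  int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i) {
    p[3*i] = pos(i,0); p[3*i+1] = pos(i,1); p[3*i+2] = pos(i,2);
  }
  Box box = parse_box(boxv, periodic);
  Pairs pr;
  build_all_pairs(s, p.data(), box, pr);
  double E[NTERM];
  std::vector<double> f(3 * n);
  eval_all(s, p.data(), box, pr, E, f);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i,0) = f[3*i]; F(i,1) = f[3*i+1]; F(i,2) = f[3*i+2];
  }
  NumericVector ev(NTERM);
  for (int t = 0; t < NTERM; ++t) ev[t] = E[t];
  ev.names() = CharacterVector::create("bond", "angle", "dihedral", "gauss13",
    "contact_go", "exv", "ele", "hps", "base_stack", "base_pair",
    "cross_stack", "pwmcos", "hb");
  return List::create(_["terms"] = ev, _["forces"] = F,
                      _["n_pairs"] = IntegerVector::create(
                        _["exv"] = (int)pr.exv_i.size(),
                        _["hps"] = (int)pr.hps_i.size(),
                        _["ele"] = (int)pr.ele_i.size(),
                        _["pwmcos"] = (int)pr.pw_s.size()));
}

// --------------------------------------------------------------- MD driver

// [[Rcpp::export]]
List cpp_run(List sysList, NumericMatrix pos0, NumericMatrix vel0,
             NumericVector boxv, bool periodic,
             int nsteps, double dt, double temperature, double gamma_fric,
             double seed, double step_offset, int nb_interval,
             int out_stride, int log_stride) {
  System s = parse_system(sysList);
  int n = pos0.nrow();
  std::vector<double> p(3*n), v(3*n), f(3*n), a(3*n);
  for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) {
    p[3*i+d] = pos0(i,d); v[3*i+d] = vel0(i,d);
  }
  Box box = parse_box(boxv, periodic);
  Pairs pr;
  build_all_pairs(s, p.data(), box, pr);
  double E[NTERM];
  eval_all(s, p.data(), box, pr, E, f);

  bool thermo = gamma_fric > 0;
  std::vector<double> noise_sd(n), inv_m(n);
  for (int i = 0; i < n; ++i) {
    inv_m[i] = 1.0 / s.mass[i];
    noise_sd[i] = thermo ?
      std::sqrt(2.0*gamma_fric*KB*temperature*ACC*inv_m[i]/dt) : 0.0;
  }
  // acceleration at current positions/velocities (A/fs^2)
  std::vector<double> xi(3*n, 0.0);
  auto accel = [&](uint64_t stepno) {
    if (thermo) {
      // one keyed Box-Muller per slot pair (cos and sin branches)
      for (int sl = 0; sl < 3*n; sl += 2) {
        uint64_t base = (uint64_t)sl >> 1;
        uint64_t k = mix64(mix64(mix64((uint64_t)seed) ^ stepno) ^
                           (0x5851F42D4C957F2DULL + base));
        double u1 = unit_open(mix64(k ^ 0xA0761D6478BD642FULL));
        double u2 = unit_open(mix64(k ^ 0xE7037ED1A0B428DBULL));
        double rr = std::sqrt(-2.0 * std::log(u1)), aa = 2.0 * M_PI * u2;
        xi[sl] = rr * std::cos(aa);
        if (sl + 1 < 3*n) xi[sl + 1] = rr * std::sin(aa);
      }
      for (int i = 0; i < n; ++i) {
        a[3*i]   = ACC*inv_m[i]*f[3*i]   - gamma_fric*v[3*i]   + noise_sd[i]*xi[3*i];
        a[3*i+1] = ACC*inv_m[i]*f[3*i+1] - gamma_fric*v[3*i+1] + noise_sd[i]*xi[3*i+1];
        a[3*i+2] = ACC*inv_m[i]*f[3*i+2] - gamma_fric*v[3*i+2] + noise_sd[i]*xi[3*i+2];
      }
    } else {
      for (int i = 0; i < n; ++i) {
        a[3*i]   = ACC*inv_m[i]*f[3*i]   - gamma_fric*v[3*i];
        a[3*i+1] = ACC*inv_m[i]*f[3*i+1] - gamma_fric*v[3*i+1];
        a[3*i+2] = ACC*inv_m[i]*f[3*i+2] - gamma_fric*v[3*i+2];
      }
    }
  };
  uint64_t abs_step = (uint64_t)step_offset;

  int nout = (out_stride > 0) ? nsteps / out_stride : 0;
  NumericMatrix traj(nout * n, 3);
  int nlog = (log_stride > 0) ? nsteps / log_stride + 1 : 0;
  NumericMatrix elog(nlog, NTERM + 3);  // step, KE, total + per-term
  int iout = 0, ilog = 0;
  auto log_state = [&](int stepno) {
    if (log_stride <= 0 || ilog >= nlog) return;
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      ke += 0.5*s.mass[i]*(v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] +
                           v[3*i+2]*v[3*i+2]);
    }
    ke /= ACC;
    double tot = 0;
    for (int t = 0; t < NTERM; ++t) tot += E[t];
    elog(ilog, 0) = stepno; elog(ilog, 1) = ke; elog(ilog, 2) = tot;
    for (int t = 0; t < NTERM; ++t) elog(ilog, 3 + t) = E[t];
    ++ilog;
  };
  log_state(0);

  for (int step = 1; step <= nsteps; ++step) {
    // a(t) recomputed from the current full-step velocity so that chunked
    // continuation runs reproduce a single run exactly
    accel(abs_step);
    ++abs_step;
    for (int i = 0; i < 3*n; ++i) v[i] += 0.5*dt*a[i];
    for (int i = 0; i < 3*n; ++i) p[i] += dt*v[i];
    if ((step % nb_interval) == 0) build_all_pairs(s, p.data(), box, pr);
    eval_all(s, p.data(), box, pr, E, f);
    accel(abs_step);
    for (int i = 0; i < 3*n; ++i) v[i] += 0.5*dt*a[i];
    for (int i = 0; i < 3*n; ++i) {
      if (!std::isfinite(p[i])) {
        stop("non-finite coordinate at step %d", step);
      }
    }
    if (out_stride > 0 && (step % out_stride) == 0 && iout < nout) {
      for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) {
        traj(iout*n + i, d) = p[3*i+d];
      }
      ++iout;
    }
    if (log_stride > 0 && (step % log_stride) == 0) log_state(step);
  }
  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) {
    pout(i,d) = p[3*i+d]; vout(i,d) = v[3*i+d];
  }
  return List::create(_["positions"] = pout, _["velocities"] = vout,
                      _["trajectory"] = traj, _["n_frames"] = iout,
                      _["energy_log"] = elog, _["n_log"] = ilog,
                      _["abs_step"] = (double)abs_step);
}
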