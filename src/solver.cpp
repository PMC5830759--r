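// Core time-stepping loop: nonlinear viscoelastic spring forces + compliant
// (XPBD-style) Gauss-Seidel constraint projection + spatial-hash collisions.
// Positions are flat row-major arrays (x[3*i + c]); node indices 0-based here,
// converted from R's 1-based indices at the wrapper boundary.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double DEGEN_EPS = 1e-9;

static inline void vset(double* o, double a, double b, double c) {
  o[0] = a; o[1] = b; o[2] = c;
}
static inline void vsub(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }
static inline void vaxpy(double s, const double* a, double* o) {
  o[0] += s * a[0]; o[1] += s * a[1]; o[2] += s * a[2];
}

// piecewise cubic/linear spring law, C1 at +/- dlc, odd
static inline double spring_scalar_c(double dl, double k1, double k2, double dlc) {
  double a = std::fabs(dl);
  if (a <= dlc) return k1 * dl + k2 * dl * dl * dl;
  double A = k1 * dlc + k2 * dlc * dlc * dlc;
  double B = k1 + 3.0 * k2 * dlc * dlc;
  return (dl > 0 ? 1.0 : -1.0) * (A + B * (a - dlc));
}

// ---------------------------------------------------------------------------
// spatial hash

static inline int hash_cell_c(long long i, long long j, long long k, int table_size) {
  long long h = (i * 73856093LL) ^ (j * 19349663LL) ^ (k * 83492791LL);
  long long m = h % (long long)table_size;
  if (m < 0) m += table_size;
  return (int)m;
}

// [[Rcpp::export]]
int cpp_hash_cell(int i, int j, int k, int table_size) {
  return hash_cell_c(i, j, k, table_size);
}

struct AABB { double mn[3], mx[3]; };

static inline bool aabb_overlap(const AABB& a, const AABB& b) {
  for (int c = 0; c < 3; ++c)
    if (a.mx[c] < b.mn[c] || b.mx[c] < a.mn[c]) return false;
  return true;
}

// broad phase over a list of AABBs; pairs deduplicated, AABB-overlap rechecked,
// pairs sharing a node excluded
static void broad_phase_c(const std::vector<AABB>& boxes,
                          const std::vector<std::vector<int> >& prim_nodes,
                          double cell_size, int table_size,
                          std::vector<std::pair<int, int> >& out) {
  int np = (int)boxes.size();
  std::vector<std::vector<int> > buckets(table_size);
  for (int p = 0; p < np; ++p) {
    long long i0 = (long long)std::floor(boxes[p].mn[0] / cell_size);
    long long i1 = (long long)std::floor(boxes[p].mx[0] / cell_size);
    long long j0 = (long long)std::floor(boxes[p].mn[1] / cell_size);
    long long j1 = (long long)std::floor(boxes[p].mx[1] / cell_size);
    long long k0 = (long long)std::floor(boxes[p].mn[2] / cell_size);
    long long k1 = (long long)std::floor(boxes[p].mx[2] / cell_size);
    for (long long i = i0; i <= i1; ++i)
      for (long long j = j0; j <= j1; ++j)
        for (long long k = k0; k <= k1; ++k)
          buckets[hash_cell_c(i, j, k, table_size)].push_back(p);
  }
  std::unordered_set<uint64_t> seen; // detection-state set: no repeat checks
  for (int b = 0; b < table_size; ++b) {
    const std::vector<int>& cell = buckets[b];
    for (size_t u = 0; u < cell.size(); ++u) {
      for (size_t v = u + 1; v < cell.size(); ++v) {
        int p = cell[u], q = cell[v];
        if (p == q) continue;
        int lo = p < q ? p : q, hi = p < q ? q : p;
        uint64_t key = (uint64_t)lo * (uint64_t)np + (uint64_t)hi;
        if (seen.count(key)) continue;
        seen.insert(key);
        if (!aabb_overlap(boxes[lo], boxes[hi])) continue;
        bool share = false;
        for (size_t a = 0; a < prim_nodes[lo].size() && !share; ++a)
          for (size_t c = 0; c < prim_nodes[hi].size(); ++c)
            if (prim_nodes[lo][a] == prim_nodes[hi][c]) { share = true; break; }
        if (share) continue;
        out.push_back(std::make_pair(lo, hi));
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_broad_phase(NumericMatrix mn, NumericMatrix mx, List prim_nodes,
                              double cell_size, int table_size) {
  int np = mn.nrow();
  std::vector<AABB> boxes(np);
  for (int p = 0; p < np; ++p)
    for (int c = 0; c < 3; ++c) {
      boxes[p].mn[c] = mn(p, c);
      boxes[p].mx[c] = mx(p, c);
    }
  std::vector<std::vector<int> > pn(np);
  for (int p = 0; p < np; ++p) {
    IntegerVector ids = prim_nodes[p];
    for (int a = 0; a < ids.size(); ++a) pn[p].push_back(ids[a]);
  }
  std::vector<std::pair<int, int> > pairs;
  broad_phase_c(boxes, pn, cell_size, table_size, pairs);
  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first + 1; // back to 1-based for R
    out(r, 1) = pairs[r].second + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// constraint evaluation + projection on flat position arrays

// exact vertex-triangle plane-distance constraint C = (q-p1).n - r and its
// analytic gradients (normal variation included; gradients sum to zero)
static bool eval_vt(const double* q, const double* p1, const double* p2,
                    const double* p3, double r,
                    double& C, double* gq, double* g1, double* g2, double* g3) {
  double u[3], e2[3], e3[3], m[3];
  vsub(q, p1, u); vsub(p2, p1, e2); vsub(p3, p1, e3);
  vcross(e2, e3, m);
  double M = vnorm(m);
  if (M < DEGEN_EPS) return false;
  double nh[3] = { m[0] / M, m[1] / M, m[2] / M };
  double s = vdot(u, m);
  C = s / M - r;
  vset(gq, nh[0], nh[1], nh[2]);
  double t1[3], t2[3];
  // d s/d e2 = e3 x u ; d|m|/d e2 = e3 x nhat
  vcross(e3, u, t1); vcross(e3, nh, t2);
  for (int c = 0; c < 3; ++c) g2[c] = (t1[c] - (s / M) * t2[c]) / M;
  // d s/d e3 = u x e2 ; d|m|/d e3 = nhat x e2
  vcross(u, e2, t1); vcross(nh, e2, t2);
  for (int c = 0; c < 3; ++c) g3[c] = (t1[c] - (s / M) * t2[c]) / M;
  for (int c = 0; c < 3; ++c) g1[c] = -(gq[c] + g2[c] + g3[c]);
  return true;
}

struct ContactSS { int i, j; double rest, lam; };
struct ContactVT { int q, p1, p2, p3; double r, lam; };

struct SolverState {
  int n;
  std::vector<double> x, xprev, xrest, w, mass;
  int degen_count;
};

// one XPBD projection of a distance-type constraint between nodes i,j
static void project_distance(std::vector<double>& x, const std::vector<double>& w,
                             int i, int j, double rest, double alpha_t,
                             double& lam, bool unilateral, int& degen) {
  double d[3];
  vsub(&x[3 * i], &x[3 * j], d);
  double L = vnorm(d);
  if (L < DEGEN_EPS) { degen++; return; }
  double C = L - rest;
  if (unilateral && C >= 0) return;
  double wi = w[i], wj = w[j];
  double denom = wi + wj + alpha_t;
  if (denom <= 0) return;
  double dlam = -(C + alpha_t * lam) / denom;
  lam += dlam;
  double nh[3] = { d[0] / L, d[1] / L, d[2] / L };
  vaxpy(wi * dlam, nh, &x[3 * i]);
  vaxpy(-wj * dlam, nh, &x[3 * j]);
}

// overstretch/compression band limiter: C = (k l0)^2 - (|d|-l0)^2, unilateral,
// rigid (alpha = 0)
static void project_overstretch(std::vector<double>& x, const std::vector<double>& w,
                                int i, int j, double l0, double kratio,
                                double& lam, int& degen) {
  double d[3];
  vsub(&x[3 * i], &x[3 * j], d);
  double L = vnorm(d);
  if (L < DEGEN_EPS) { degen++; return; }
  double dl = L - l0, band = kratio * l0;
  if (dl * dl <= band * band) return;
  double C = band * band - dl * dl;
  double gfac = -2.0 * dl / L; // grad_i = gfac * d, grad_j = -gfac * d
  double g2 = gfac * gfac * vdot(d, d);
  double denom = (w[i] + w[j]) * g2;
  if (denom <= 0) return;
  double dlam = -C / denom;
  lam += dlam;
  vaxpy(w[i] * dlam * gfac, d, &x[3 * i]);
  vaxpy(-w[j] * dlam * gfac, d, &x[3 * j]);
}

static void project_tet(std::vector<double>& x, const std::vector<double>& w,
                        const int* id, double V0, double alpha_t, double& lam) {
  double e2[3], e3[3], e4[3];
  const double* p1 = &x[3 * id[0]];
  vsub(&x[3 * id[1]], p1, e2);
  vsub(&x[3 * id[2]], p1, e3);
  vsub(&x[3 * id[3]], p1, e4);
  double c23[3];
  vcross(e2, e3, c23);
  double C = vdot(c23, e4) / 6.0 - V0;
  double g2[3], g3[3], g4[3], g1[3];
  vcross(e3, e4, g2); vcross(e4, e2, g3); vcross(e2, e3, g4);
  for (int c = 0; c < 3; ++c) {
    g2[c] /= 6.0; g3[c] /= 6.0; g4[c] /= 6.0;
    g1[c] = -(g2[c] + g3[c] + g4[c]);
  }
  double denom = w[id[0]] * vdot(g1, g1) + w[id[1]] * vdot(g2, g2) +
                 w[id[2]] * vdot(g3, g3) + w[id[3]] * vdot(g4, g4) + alpha_t;
  if (denom <= 0) return;
  double dlam = -(C + alpha_t * lam) / denom;
  lam += dlam;
  vaxpy(w[id[0]] * dlam, g1, &x[3 * id[0]]);
  vaxpy(w[id[1]] * dlam, g2, &x[3 * id[1]]);
  vaxpy(w[id[2]] * dlam, g3, &x[3 * id[2]]);
  vaxpy(w[id[3]] * dlam, g4, &x[3 * id[3]]);
}

// global closed-surface volume constraint; grad buffer is n*3, zeroed here
static void project_surfvol(std::vector<double>& x, const std::vector<double>& w,
                            const std::vector<int>& tris, double V0, double alpha_t,
                            double& lam, std::vector<double>& grad,
                            const std::vector<int>& touched) {
  for (size_t a = 0; a < touched.size(); ++a) {
    int v = touched[a];
    grad[3 * v] = grad[3 * v + 1] = grad[3 * v + 2] = 0.0;
  }
  double V = 0.0;
  int nt = (int)tris.size() / 3;
  for (int t = 0; t < nt; ++t) {
    int a = tris[3 * t], b = tris[3 * t + 1], c = tris[3 * t + 2];
    const double* pa = &x[3 * a];
    const double* pb = &x[3 * b];
    const double* pc = &x[3 * c];
    double cab[3], cbc[3], cca[3];
    vcross(pa, pb, cab); vcross(pb, pc, cbc); vcross(pc, pa, cca);
    V += vdot(cab, pc) / 6.0;
    vaxpy(1.0 / 6.0, cbc, &grad[3 * a]);
    vaxpy(1.0 / 6.0, cca, &grad[3 * b]);
    vaxpy(1.0 / 6.0, cab, &grad[3 * c]);
  }
  double C = V - V0;
  double denom = alpha_t;
  for (size_t a = 0; a < touched.size(); ++a) {
    int v = touched[a];
    denom += w[v] * vdot(&grad[3 * v], &grad[3 * v]);
  }
  if (denom <= 0) return;
  double dlam = -(C + alpha_t * lam) / denom;
  lam += dlam;
  for (size_t a = 0; a < touched.size(); ++a) {
    int v = touched[a];
    vaxpy(w[v] * dlam, &grad[3 * v], &x[3 * v]);
  }
}

static void project_vt(std::vector<double>& x, const std::vector<double>& w,
                       ContactVT& ct, int& degen) {
  double C, gq[3], g1[3], g2[3], g3[3];
  if (!eval_vt(&x[3 * ct.q], &x[3 * ct.p1], &x[3 * ct.p2], &x[3 * ct.p3], ct.r,
               C, gq, g1, g2, g3)) { degen++; return; }
  if (C >= 0) return; // unilateral
  double denom = w[ct.q] * vdot(gq, gq) + w[ct.p1] * vdot(g1, g1) +
                 w[ct.p2] * vdot(g2, g2) + w[ct.p3] * vdot(g3, g3);
  if (denom <= 0) return;
  double dlam = -C / denom;
  ct.lam += dlam;
  vaxpy(w[ct.q] * dlam, gq, &x[3 * ct.q]);
  vaxpy(w[ct.p1] * dlam, g1, &x[3 * ct.p1]);
  vaxpy(w[ct.p2] * dlam, g2, &x[3 * ct.p2]);
  vaxpy(w[ct.p3] * dlam, g3, &x[3 * ct.p3]);
}

// ---------------------------------------------------------------------------
// full stepper

// [[Rcpp::export]]
List cpp_run(List sys, List spr, List cons, List coll, List bcl, List cfg) {
  // --- unpack particle system
  NumericMatrix X = sys["x"], XP = sys["x_prev"], XR = sys["x_rest"];
  NumericVector W = sys["w"], MASS = sys["mass"];
  int n = X.nrow();
  std::vector<double> x(3 * n), xprev(3 * n), xrest(3 * n), w(n), mass(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) {
      x[3 * i + c] = X(i, c);
      xprev[3 * i + c] = XP(i, c);
      xrest[3 * i + c] = XR(i, c);
    }
    w[i] = W[i];
    mass[i] = MASS[i];
  }

  // --- springs (0-based index matrix from wrapper)
  IntegerMatrix SP = spr["nodes"];
  NumericVector SL0 = spr["l0"], SDLC = spr["dl_c"];
  int ns = SP.nrow();
  std::vector<int> sp_i(ns), sp_j(ns);
  std::vector<double> sp_l0(ns), sp_dlc(ns);
  for (int s = 0; s < ns; ++s) {
    sp_i[s] = SP(s, 0); sp_j[s] = SP(s, 1);
    sp_l0[s] = SL0[s]; sp_dlc[s] = SDLC[s];
  }
  double k1 = as<double>(spr["k1"]), k2 = as<double>(spr["k2"]);
  double b0 = as<double>(spr["b0"]), b1 = as<double>(spr["b1"]);

  // --- persistent constraints
  NumericMatrix DC = cons["dist"];      // i j rest alpha
  NumericMatrix OC = cons["over"];      // i j l0 kratio
  NumericMatrix TC = cons["tet"];       // i1..i4 V0 alpha
  int ndc = DC.nrow(), noc = OC.nrow(), ntc = TC.nrow();
  bool has_sv = as<bool>(cons["has_surf"]);
  std::vector<int> sv_tris, sv_touched;
  double sv_V0 = 0.0, sv_alpha = 0.0;
  if (has_sv) {
    IntegerMatrix ST = cons["surf_tris"];
    sv_V0 = as<double>(cons["surf_V0"]);
    sv_alpha = as<double>(cons["surf_alpha"]);
    std::vector<bool> seen(n, false);
    for (int t = 0; t < ST.nrow(); ++t)
      for (int c = 0; c < 3; ++c) {
        sv_tris.push_back(ST(t, c));
        if (!seen[ST(t, c)]) { seen[ST(t, c)] = true; sv_touched.push_back(ST(t, c)); }
      }
  }
  std::vector<double> lam_d(ndc), lam_o(noc), lam_t(ntc);
  double lam_sv = 0.0;
  std::vector<double> sv_grad(3 * n, 0.0);

  // --- collision config
  bool coll_on = as<bool>(coll["enabled"]);
  std::vector<int> sph_nodes;
  std::vector<double> sph_r;
  std::vector<int> ctri; // collision triangles, flat
  double cell_size = 1.0, margin = 0.0, tri_r = 0.0;
  int table_size = 1;
  if (coll_on) {
    IntegerVector SN = coll["sphere_nodes"];
    NumericVector SR = coll["sphere_r"];
    IntegerMatrix CT = coll["tri"];
    for (int a = 0; a < SN.size(); ++a) { sph_nodes.push_back(SN[a]); sph_r.push_back(SR[a]); }
    for (int t = 0; t < CT.nrow(); ++t)
      for (int c = 0; c < 3; ++c) ctri.push_back(CT(t, c));
    cell_size = as<double>(coll["cell_size"]);
    table_size = as<int>(coll["table_size"]);
    margin = as<double>(coll["margin"]);
    tri_r = as<double>(coll["tri_margin"]);
  }
  int nsph = (int)sph_nodes.size(), nctri = (int)ctri.size() / 3;

  // --- boundary conditions: kind 0 fixed, 1 velocity, 2 force
  int nbc = bcl.size();
  std::vector<int> bc_kind(nbc);
  std::vector<std::vector<int> > bc_nodes(nbc);
  std::vector<double> bc_t0(nbc), bc_t1(nbc);
  std::vector<std::array<double, 3> > bc_val(nbc);
  for (int b = 0; b < nbc; ++b) {
    List bc = bcl[b];
    bc_kind[b] = as<int>(bc["kind"]);
    IntegerVector ids = bc["nodes"];
    for (int a = 0; a < ids.size(); ++a) bc_nodes[b].push_back(ids[a]);
    NumericVector v = bc["value"];
    bc_val[b] = { v[0], v[1], v[2] };
    bc_t0[b] = as<double>(bc["t0"]);
    bc_t1[b] = as<double>(bc["t1"]);
  }

  // --- solver config
  double dt = as<double>(cfg["dt"]);
  int iterations = as<int>(cfg["iterations"]);
  int n_steps = as<int>(cfg["n_steps"]);
  int stride = as<int>(cfg["stride"]);
  double t_start = as<double>(cfg["t_start"]);
  NumericVector GV = cfg["gravity"];
  double grav[3] = { GV[0], GV[1], GV[2] };
  int probe = as<int>(cfg["probe"]); // 0-based, -1 = none
  bool half_start = as<bool>(cfg["half_start"]);
  int vol_kind = as<int>(cfg["vol_kind"]); // 0 none, 1 tet list, 2 surface list
  std::vector<int> vol_idx;
  if (vol_kind == 1) {
    IntegerMatrix VT = cfg["vol_tets"];
    for (int t = 0; t < VT.nrow(); ++t)
      for (int c = 0; c < 4; ++c) vol_idx.push_back(VT(t, c));
  } else if (vol_kind == 2) {
    IntegerMatrix VS = cfg["vol_tris"];
    for (int t = 0; t < VS.nrow(); ++t)
      for (int c = 0; c < 3; ++c) vol_idx.push_back(VS(t, c));
  }

  int n_rec = (stride > 0) ? (n_steps / stride) : 0;
  NumericMatrix series(n_rec, 14);
  colnames(series) = CharacterVector::create(
    "t", "px", "py", "pz", "disp", "fx", "fy", "fz", "fmag",
    "volume", "max_C", "n_contacts", "kinetic_energy", "bbox_diag");
  int rec = 0;
  int degen = 0;

  std::vector<double> f(3 * n), effw(n);
  std::vector<ContactSS> css;
  std::vector<ContactVT> cvt;

  for (int step = 0; step < n_steps; ++step) {
    double t = t_start + step * dt;

    // effective inverse masses under active BCs
    for (int i = 0; i < n; ++i) effw[i] = w[i];
    for (int b = 0; b < nbc; ++b) {
      if (t < bc_t0[b] - 1e-12 || t >= bc_t1[b] - 1e-12) continue;
      if (bc_kind[b] == 0 || bc_kind[b] == 1)
        for (size_t a = 0; a < bc_nodes[b].size(); ++a) effw[bc_nodes[b][a]] = 0.0;
    }

    // forces: gravity + applied + springs (damper handled implicitly below)
    for (int i = 0; i < n; ++i) {
      double m = mass[i];
      f[3 * i] = m * grav[0]; f[3 * i + 1] = m * grav[1]; f[3 * i + 2] = m * grav[2];
    }
    for (int b = 0; b < nbc; ++b) {
      if (bc_kind[b] != 2) continue;
      if (t < bc_t0[b] - 1e-12 || t >= bc_t1[b] - 1e-12) continue;
      for (size_t a = 0; a < bc_nodes[b].size(); ++a) {
        int i = bc_nodes[b][a];
        f[3 * i] += bc_val[b][0]; f[3 * i + 1] += bc_val[b][1]; f[3 * i + 2] += bc_val[b][2];
      }
    }
    for (int s = 0; s < ns; ++s) {
      double d[3];
      vsub(&x[3 * sp_i[s]], &x[3 * sp_j[s]], d);
      double L = vnorm(d);
      if (L < DEGEN_EPS) { degen++; continue; }
      double fs = spring_scalar_c(L - sp_l0[s], k1, k2, sp_dlc[s]);
      // restoring: pull i toward j when stretched
      double sc = -fs / L;
      vaxpy(sc, d, &f[3 * sp_i[s]]);
      vaxpy(-sc, d, &f[3 * sp_j[s]]);
    }

    // probe bookkeeping: internal spring + damper force before prediction
    double probe_fsd[3] = { 0, 0, 0 };
    if (probe >= 0) {
      probe_fsd[0] = f[3 * probe] - mass[probe] * grav[0];
      probe_fsd[1] = f[3 * probe + 1] - mass[probe] * grav[1];
      probe_fsd[2] = f[3 * probe + 2] - mass[probe] * grav[2];
      double dr[3], v[3];
      vsub(&x[3 * probe], &xrest[3 * probe], dr);
      vsub(&x[3 * probe], &xprev[3 * probe], v);
      double bco = b0 + b1 * vnorm(dr);
      for (int c = 0; c < 3; ++c) probe_fsd[c] += -bco * v[c] / dt;
    }

    // standard Verlet half-step start: shift x_prev so the first step carries
    // half an acceleration increment (exact for constant forces)
    if (step == 0 && half_start)
      for (int i = 0; i < n; ++i) {
        if (effw[i] <= 0) continue;
        for (int c = 0; c < 3; ++c)
          xprev[3 * i + c] += 0.5 * effw[i] * f[3 * i + c] * dt * dt;
      }

    // predict x*: semi-implicit rest-referenced drag on the inertial term
    std::vector<double> xs(x);
    for (int i = 0; i < n; ++i) {
      if (effw[i] <= 0) continue;
      double dr[3];
      vsub(&x[3 * i], &xrest[3 * i], dr);
      double gamma = (b0 + b1 * vnorm(dr)) * dt * effw[i];
      double inert = 1.0 / (1.0 + gamma);
      for (int c = 0; c < 3; ++c) {
        double xi = x[3 * i + c];
        xs[3 * i + c] = xi + ((xi - xprev[3 * i + c]) +
                              effw[i] * f[3 * i + c] * dt * dt) * inert;
      }
    }
    // kinematically driven nodes
    for (int b = 0; b < nbc; ++b) {
      if (bc_kind[b] != 1) continue;
      if (t < bc_t0[b] - 1e-12 || t >= bc_t1[b] - 1e-12) continue;
      for (size_t a = 0; a < bc_nodes[b].size(); ++a) {
        int i = bc_nodes[b][a];
        for (int c = 0; c < 3; ++c) xs[3 * i + c] = x[3 * i + c] + bc_val[b][c] * dt;
      }
    }

    // collision detection on predicted positions -> transient contacts
    css.clear(); cvt.clear();
    if (coll_on && (nsph > 0) && (nsph + nctri > 1)) {
      int np = nsph + nctri;
      std::vector<AABB> boxes(np);
      std::vector<std::vector<int> > pn(np);
      for (int a = 0; a < nsph; ++a) {
        int node = sph_nodes[a];
        for (int c = 0; c < 3; ++c) {
          boxes[a].mn[c] = xs[3 * node + c] - sph_r[a] - margin;
          boxes[a].mx[c] = xs[3 * node + c] + sph_r[a] + margin;
        }
        pn[a].push_back(node);
      }
      for (int tI = 0; tI < nctri; ++tI) {
        AABB& bx = boxes[nsph + tI];
        for (int c = 0; c < 3; ++c) { bx.mn[c] = R_PosInf; bx.mx[c] = R_NegInf; }
        for (int vv = 0; vv < 3; ++vv) {
          int node = ctri[3 * tI + vv];
          pn[nsph + tI].push_back(node);
          for (int c = 0; c < 3; ++c) {
            double p = xs[3 * node + c];
            if (p - margin < bx.mn[c]) bx.mn[c] = p - margin;
            if (p + margin > bx.mx[c]) bx.mx[c] = p + margin;
          }
        }
      }
      std::vector<std::pair<int, int> > pairs;
      broad_phase_c(boxes, pn, cell_size, table_size, pairs);
      for (size_t r = 0; r < pairs.size(); ++r) {
        int p = pairs[r].first, q = pairs[r].second;
        bool psph = p < nsph, qsph = q < nsph;
        if (psph && qsph) {
          int ni = sph_nodes[p], nj = sph_nodes[q];
          double d[3];
          vsub(&xs[3 * ni], &xs[3 * nj], d);
          double L = vnorm(d), rsum = sph_r[p] + sph_r[q];
          if (L < rsum) { // strict penetration
            ContactSS ct; ct.i = ni; ct.j = nj; ct.rest = rsum; ct.lam = 0.0;
            css.push_back(ct);
          }
        } else if (psph != qsph) {
          int sp = psph ? p : q, tq = (psph ? q : p) - nsph;
          int node = sph_nodes[sp];
          int a = ctri[3 * tq], bb = ctri[3 * tq + 1], cc = ctri[3 * tq + 2];
          double C, gq[3], g1[3], g2[3], g3[3];
          if (!eval_vt(&xs[3 * node], &xs[3 * a], &xs[3 * bb], &xs[3 * cc],
                       sph_r[sp], C, gq, g1, g2, g3)) continue;
          if (C >= 0) continue;
          // barycentric face-interior test of the projected centre
          double e2[3], e3[3], u[3];
          vsub(&xs[3 * bb], &xs[3 * a], e2);
          vsub(&xs[3 * cc], &xs[3 * a], e3);
          vsub(&xs[3 * node], &xs[3 * a], u);
          double d22 = vdot(e2, e2), d23 = vdot(e2, e3), d33 = vdot(e3, e3);
          double du2 = vdot(u, e2), du3 = vdot(u, e3);
          double det = d22 * d33 - d23 * d23;
          if (det <= 0) continue;
          double wb = (d33 * du2 - d23 * du3) / det;
          double wc = (d22 * du3 - d23 * du2) / det;
          if (wb < 0 || wc < 0 || wb + wc > 1) continue;
          ContactVT ct; ct.q = node; ct.p1 = a; ct.p2 = bb; ct.p3 = cc;
          ct.r = sph_r[sp]; ct.lam = 0.0;
          cvt.push_back(ct);
        } else {
          // triangle-triangle: three vertex-triangle tests (first's vertices vs second)
          int ta = p - nsph, tb = q - nsph;
          for (int vv = 0; vv < 3; ++vv) {
            int node = ctri[3 * ta + vv];
            int a = ctri[3 * tb], bb = ctri[3 * tb + 1], cc = ctri[3 * tb + 2];
            double C, gq[3], g1[3], g2[3], g3[3];
            if (!eval_vt(&xs[3 * node], &xs[3 * a], &xs[3 * bb], &xs[3 * cc],
                         tri_r, C, gq, g1, g2, g3)) continue;
            if (C >= 0) continue;
            ContactVT ct; ct.q = node; ct.p1 = a; ct.p2 = bb; ct.p3 = cc;
            ct.r = tri_r; ct.lam = 0.0;
            cvt.push_back(ct);
          }
        }
      }
    }

    // reset multipliers (XPBD convention), then Gauss-Seidel projection loop
    std::fill(lam_d.begin(), lam_d.end(), 0.0);
    std::fill(lam_o.begin(), lam_o.end(), 0.0);
    std::fill(lam_t.begin(), lam_t.end(), 0.0);
    lam_sv = 0.0;
    double at_fac = 1.0 / (dt * dt);
    for (int it = 0; it < iterations; ++it) {
      for (int cI = 0; cI < ndc; ++cI)
        project_distance(xs, effw, (int)DC(cI, 0), (int)DC(cI, 1), DC(cI, 2),
                         DC(cI, 3) * at_fac, lam_d[cI], false, degen);
      for (int cI = 0; cI < noc; ++cI)
        project_overstretch(xs, effw, (int)OC(cI, 0), (int)OC(cI, 1), OC(cI, 2),
                            OC(cI, 3), lam_o[cI], degen);
      for (int cI = 0; cI < ntc; ++cI) {
        int id[4] = { (int)TC(cI, 0), (int)TC(cI, 1), (int)TC(cI, 2), (int)TC(cI, 3) };
        project_tet(xs, effw, id, TC(cI, 4), TC(cI, 5) * at_fac, lam_t[cI]);
      }
      if (has_sv)
        project_surfvol(xs, effw, sv_tris, sv_V0, sv_alpha * at_fac, lam_sv,
                        sv_grad, sv_touched);
      for (size_t cI = 0; cI < css.size(); ++cI)
        project_distance(xs, effw, css[cI].i, css[cI].j, css[cI].rest, 0.0,
                         css[cI].lam, true, degen);
      for (size_t cI = 0; cI < cvt.size(); ++cI)
        project_vt(xs, effw, cvt[cI], degen);
    }

    // finiteness check before committing
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        if (!std::isfinite(xs[3 * i + c]))
          stop("solver-error: non-finite position at node %d, step %d", i + 1, step + 1);

    bool record = (stride > 0) && ((step + 1) % stride == 0);
    if (record) {
      double tr = t + dt;
      series(rec, 0) = tr;
      if (probe >= 0) {
        series(rec, 1) = xs[3 * probe];
        series(rec, 2) = xs[3 * probe + 1];
        series(rec, 3) = xs[3 * probe + 2];
        double dr[3];
        vsub(&xs[3 * probe], &xrest[3 * probe], dr);
        series(rec, 4) = vnorm(dr);
        // reaction = m a - f_internal (spring + damper + constraint forces)
        double fc[3] = { 0, 0, 0 };
        double lfac = 1.0 / (dt * dt);
        for (int cI = 0; cI < ndc; ++cI) {
          int i = (int)DC(cI, 0), j = (int)DC(cI, 1);
          if (i != probe && j != probe) continue;
          double d[3];
          vsub(&xs[3 * i], &xs[3 * j], d);
          double L = vnorm(d);
          if (L < DEGEN_EPS) continue;
          double sgn = (i == probe) ? 1.0 : -1.0;
          vaxpy(sgn * lam_d[cI] * lfac / L, d, fc);
        }
        for (int cI = 0; cI < noc; ++cI) {
          int i = (int)OC(cI, 0), j = (int)OC(cI, 1);
          if (i != probe && j != probe) continue;
          double d[3];
          vsub(&xs[3 * i], &xs[3 * j], d);
          double L = vnorm(d);
          if (L < DEGEN_EPS) continue;
          double dl = L - OC(cI, 2);
          double gfac = -2.0 * dl / L;
          double sgn = (i == probe) ? 1.0 : -1.0;
          vaxpy(sgn * lam_o[cI] * lfac * gfac, d, fc);
        }
        for (int cI = 0; cI < ntc; ++cI) {
          int id[4] = { (int)TC(cI, 0), (int)TC(cI, 1), (int)TC(cI, 2), (int)TC(cI, 3) };
          int which = -1;
          for (int a = 0; a < 4; ++a) if (id[a] == probe) which = a;
          if (which < 0) continue;
          double e2[3], e3[3], e4[3], g2[3], g3[3], g4[3], g1[3];
          const double* p1 = &xs[3 * id[0]];
          vsub(&xs[3 * id[1]], p1, e2);
          vsub(&xs[3 * id[2]], p1, e3);
          vsub(&xs[3 * id[3]], p1, e4);
          vcross(e3, e4, g2); vcross(e4, e2, g3); vcross(e2, e3, g4);
          for (int c = 0; c < 3; ++c) {
            g2[c] /= 6.0; g3[c] /= 6.0; g4[c] /= 6.0;
            g1[c] = -(g2[c] + g3[c] + g4[c]);
          }
          double* gg = (which == 0) ? g1 : (which == 1) ? g2 : (which == 2) ? g3 : g4;
          vaxpy(lam_t[cI] * lfac, gg, fc);
        }
        if (has_sv) {
          bool touches = false;
          for (size_t a = 0; a < sv_touched.size(); ++a)
            if (sv_touched[a] == probe) { touches = true; break; }
          if (touches) {
            // sv_grad holds last-iteration gradients at current xs (close enough:
            // recompute for exactness)
            for (size_t a = 0; a < sv_touched.size(); ++a) {
              int v = sv_touched[a];
              sv_grad[3 * v] = sv_grad[3 * v + 1] = sv_grad[3 * v + 2] = 0.0;
            }
            int nt2 = (int)sv_tris.size() / 3;
            for (int t2 = 0; t2 < nt2; ++t2) {
              int a = sv_tris[3 * t2], b = sv_tris[3 * t2 + 1], c = sv_tris[3 * t2 + 2];
              double cab[3], cbc[3], cca[3];
              vcross(&xs[3 * a], &xs[3 * b], cab);
              vcross(&xs[3 * b], &xs[3 * c], cbc);
              vcross(&xs[3 * c], &xs[3 * a], cca);
              vaxpy(1.0 / 6.0, cbc, &sv_grad[3 * a]);
              vaxpy(1.0 / 6.0, cca, &sv_grad[3 * b]);
              vaxpy(1.0 / 6.0, cab, &sv_grad[3 * c]);
            }
            vaxpy(lam_sv * lfac, &sv_grad[3 * probe], fc);
          }
        }
        for (size_t cI = 0; cI < css.size(); ++cI) {
          if (css[cI].i != probe && css[cI].j != probe) continue;
          double d[3];
          vsub(&xs[3 * css[cI].i], &xs[3 * css[cI].j], d);
          double L = vnorm(d);
          if (L < DEGEN_EPS) continue;
          double sgn = (css[cI].i == probe) ? 1.0 : -1.0;
          vaxpy(sgn * css[cI].lam * lfac / L, d, fc);
        }
        for (size_t cI = 0; cI < cvt.size(); ++cI) {
          ContactVT& ct = cvt[cI];
          int which = (ct.q == probe) ? 0 : (ct.p1 == probe) ? 1 :
                      (ct.p2 == probe) ? 2 : (ct.p3 == probe) ? 3 : -1;
          if (which < 0) continue;
          double C, gq[3], g1[3], g2[3], g3[3];
          if (!eval_vt(&xs[3 * ct.q], &xs[3 * ct.p1], &xs[3 * ct.p2],
                       &xs[3 * ct.p3], ct.r, C, gq, g1, g2, g3)) continue;
          double* gg = (which == 0) ? gq : (which == 1) ? g1 : (which == 2) ? g2 : g3;
          vaxpy(ct.lam * lfac, gg, fc);
        }
        double acc[3], rf[3];
        for (int c = 0; c < 3; ++c) {
          acc[c] = (xs[3 * probe + c] - 2.0 * x[3 * probe + c] + xprev[3 * probe + c]) /
                   (dt * dt);
          rf[c] = mass[probe] * acc[c] - probe_fsd[c] - fc[c];
        }
        series(rec, 5) = rf[0]; series(rec, 6) = rf[1]; series(rec, 7) = rf[2];
        series(rec, 8) = vnorm(rf);
      } else {
        for (int c = 1; c <= 8; ++c) series(rec, c) = NA_REAL;
      }

      // mesh volume
      double vol = NA_REAL;
      if (vol_kind == 1) {
        vol = 0.0;
        int ntt = (int)vol_idx.size() / 4;
        for (int t2 = 0; t2 < ntt; ++t2) {
          const double* p1 = &xs[3 * vol_idx[4 * t2]];
          double e2[3], e3[3], e4[3], c23[3];
          vsub(&xs[3 * vol_idx[4 * t2 + 1]], p1, e2);
          vsub(&xs[3 * vol_idx[4 * t2 + 2]], p1, e3);
          vsub(&xs[3 * vol_idx[4 * t2 + 3]], p1, e4);
          vcross(e2, e3, c23);
          vol += vdot(c23, e4) / 6.0;
        }
      } else if (vol_kind == 2) {
        vol = 0.0;
        int ntt = (int)vol_idx.size() / 3;
        for (int t2 = 0; t2 < ntt; ++t2) {
          double cab[3];
          vcross(&xs[3 * vol_idx[3 * t2]], &xs[3 * vol_idx[3 * t2 + 1]], cab);
          vol += vdot(cab, &xs[3 * vol_idx[3 * t2 + 2]]) / 6.0;
        }
      }
      series(rec, 9) = vol;

      // residual |C| over persistent bilateral constraints + contact penetration
      double maxC = 0.0;
      for (int cI = 0; cI < ndc; ++cI) {
        double d[3];
        vsub(&xs[3 * (int)DC(cI, 0)], &xs[3 * (int)DC(cI, 1)], d);
        double C = vnorm(d) - DC(cI, 2);
        if (std::fabs(C) > maxC) maxC = std::fabs(C);
      }
      for (int cI = 0; cI < ntc; ++cI) {
        int id[4] = { (int)TC(cI, 0), (int)TC(cI, 1), (int)TC(cI, 2), (int)TC(cI, 3) };
        const double* p1 = &xs[3 * id[0]];
        double e2[3], e3[3], e4[3], c23[3];
        vsub(&xs[3 * id[1]], p1, e2);
        vsub(&xs[3 * id[2]], p1, e3);
        vsub(&xs[3 * id[3]], p1, e4);
        vcross(e2, e3, c23);
        double C = vdot(c23, e4) / 6.0 - TC(cI, 4);
        if (std::fabs(C) > maxC) maxC = std::fabs(C);
      }
      for (size_t cI = 0; cI < css.size(); ++cI) {
        double d[3];
        vsub(&xs[3 * css[cI].i], &xs[3 * css[cI].j], d);
        double C = vnorm(d) - css[cI].rest;
        if (C < 0 && -C > maxC) maxC = -C;
      }
      for (size_t cI = 0; cI < cvt.size(); ++cI) {
        double C, gq[3], g1[3], g2[3], g3[3];
        if (eval_vt(&xs[3 * cvt[cI].q], &xs[3 * cvt[cI].p1], &xs[3 * cvt[cI].p2],
                    &xs[3 * cvt[cI].p3], cvt[cI].r, C, gq, g1, g2, g3))
          if (C < 0 && -C > maxC) maxC = -C;
      }
      series(rec, 10) = maxC;
      series(rec, 11) = (double)(css.size() + cvt.size());

      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        if (mass[i] <= 0) continue;
        double v[3];
        for (int c = 0; c < 3; ++c) v[c] = (xs[3 * i + c] - x[3 * i + c]) / dt;
        ke += 0.5 * mass[i] * vdot(v, v);
      }
      series(rec, 12) = ke;

      double bmn[3] = { R_PosInf, R_PosInf, R_PosInf };
      double bmx[3] = { R_NegInf, R_NegInf, R_NegInf };
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) {
          if (xs[3 * i + c] < bmn[c]) bmn[c] = xs[3 * i + c];
          if (xs[3 * i + c] > bmx[c]) bmx[c] = xs[3 * i + c];
        }
      double dsum = 0.0;
      for (int c = 0; c < 3; ++c) dsum += (bmx[c] - bmn[c]) * (bmx[c] - bmn[c]);
      series(rec, 13) = std::sqrt(dsum);
      rec++;
    }

    // commit
    xprev = x;
    x = xs;
  }

  NumericMatrix Xo(n, 3), XPo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      Xo(i, c) = x[3 * i + c];
      XPo(i, c) = xprev[3 * i + c];
    }
  return List::create(_["x"] = Xo, _["x_prev"] = XPo, _["series"] = series,
                      _["degenerate_events"] = degen);
}
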