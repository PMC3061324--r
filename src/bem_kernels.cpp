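// Galerkin BEM kernels: analytic triangle integrals for the Laplace single and
// (linear) double layer, adaptive outer quadrature, dipole source integrals,
// Biot-Savart surface integrals, point-in-mesh winding numbers, closest-point
// queries and a small incremental 3D convex hull (used for random sphere meshes).
//
// Conventions (validated end-to-end against the concentric-sphere oracles):
//   G(r,r')      = 1/(4*pi*||r-r'||)
//   d_{n'}G      = n'.(r-r') / (4*pi*||r-r'||^3)   (derivative w.r.t. source point)
//   solid angle  SA(x,T) = int_T (y-x).n / ||y-x||^3 dS(y)
// so that a closed outward-oriented surface seen from inside has total SA = 4*pi.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef arma::vec::fixed<3> V3;

static inline double dot3(const V3& a, const V3& b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline V3 cross3(const V3& a, const V3& b) {
  V3 c;
  c[0] = a[1]*b[2] - a[2]*b[1];
  c[1] = a[2]*b[0] - a[0]*b[2];
  c[2] = a[0]*b[1] - a[1]*b[0];
  return c;
}
static inline double norm3(const V3& a) { return std::sqrt(dot3(a, a)); }

static const double FOURPI = 4.0 * M_PI;

// ---------------------------------------------------------------------------
// Triangle geometry cache
// ---------------------------------------------------------------------------

struct Tri {
  V3 p[3];
  V3 n;        // unit normal (right-hand rule on vertex order)
  V3 cen;
  double area;
  double diam; // longest edge
  V3 g[3];     // in-plane gradients of the P1 shape functions
};

static std::vector<Tri> build_tris(const arma::mat& V, const arma::imat& F) {
  const arma::uword nT = F.n_rows;
  std::vector<Tri> tris(nT);
  for (arma::uword t = 0; t < nT; ++t) {
    Tri& tr = tris[t];
    for (int j = 0; j < 3; ++j) {
      int v = F(t, j) - 1; // R is 1-based
      tr.p[j][0] = V(v, 0); tr.p[j][1] = V(v, 1); tr.p[j][2] = V(v, 2);
    }
    V3 e01 = tr.p[1] - tr.p[0], e02 = tr.p[2] - tr.p[0], e12 = tr.p[2] - tr.p[1];
    V3 cr = cross3(e01, e02);
    double twoA = norm3(cr);
    tr.area = 0.5 * twoA;
    tr.n = cr / twoA;
    tr.cen = (tr.p[0] + tr.p[1] + tr.p[2]) / 3.0;
    tr.diam = std::max(norm3(e01), std::max(norm3(e02), norm3(e12)));
    // grad phi_i = n x (p_k - p_j) / (2A), (i,j,k) cyclic
    tr.g[0] = cross3(tr.n, tr.p[2] - tr.p[1]) / twoA;
    tr.g[1] = cross3(tr.n, tr.p[0] - tr.p[2]) / twoA;
    tr.g[2] = cross3(tr.n, tr.p[1] - tr.p[0]) / twoA;
  }
  return tris;
}

// ---------------------------------------------------------------------------
// Analytic integrals of a flat triangle at an observation point x
//   S  = int_T 1/||x-y|| dS(y)
//   A_i= int_T phi_i(y) (x-y).n / ||x-y||^3 dS(y)   (principal value: 0 when x
//        lies in the triangle's plane)
//   SA = int_T (y-x).n / ||x-y||^3 dS(y)            (signed solid angle)
// ---------------------------------------------------------------------------

static inline double solid_angle(const Tri& t, const V3& x) {
  V3 w0 = t.p[0] - x, w1 = t.p[1] - x, w2 = t.p[2] - x;
  double r0 = norm3(w0), r1 = norm3(w1), r2 = norm3(w2);
  double num = dot3(w0, cross3(w1, w2));
  double den = r0*r1*r2 + r2*dot3(w0, w1) + r1*dot3(w0, w2) + r0*dot3(w1, w2);
  return 2.0 * std::atan2(num, den);
}

struct Ana { double S; double A[3]; double SA; };

static void tri_analytic(const Tri& t, const V3& x, Ana& o) {
  double SA = solid_angle(t, x);
  double d = dot3(t.n, x - t.p[0]);
  V3 P = x - d * t.n;

  double Ssum = 0.0;
  double eacc[3] = {0.0, 0.0, 0.0};
  for (int e = 0; e < 3; ++e) {
    const V3& a = t.p[e];
    const V3& b = t.p[(e + 1) % 3];
    V3 ab = b - a;
    double len = norm3(ab);
    V3 tt = ab / len;
    V3 m = cross3(tt, t.n); // outward in-plane edge normal
    V3 aP = a - P;
    double P0 = dot3(aP, m);
    double lm = dot3(aP, tt);
    double lp = dot3(b - P, tt);
    double Rm = norm3(x - a);
    double Rp = norm3(x - b);
    double L;
    if (lp + lm >= 0.0) {
      double nu = Rp + lp, de = Rm + lm;
      L = (nu > 0.0 && de > 0.0) ? std::log(nu / de) : 0.0;
    } else {
      double nu = Rm - lm, de = Rp - lp;
      L = (nu > 0.0 && de > 0.0) ? std::log(nu / de) : 0.0;
    }
    Ssum += P0 * L;
    for (int i = 0; i < 3; ++i) eacc[i] += dot3(t.g[i], m) * L;
  }
  o.S = Ssum + d * SA;
  o.SA = SA;

  if (std::fabs(d) <= 1e-12 * t.diam) {
    o.A[0] = o.A[1] = o.A[2] = 0.0; // principal value on the plane
    return;
  }
  // barycentric coordinates of P (affine extension of phi)
  V3 v0 = t.p[1] - t.p[0], v1 = t.p[2] - t.p[0], v2 = P - t.p[0];
  double d00 = dot3(v0, v0), d01 = dot3(v0, v1), d11 = dot3(v1, v1);
  double d20 = dot3(v2, v0), d21 = dot3(v2, v1);
  double inv = 1.0 / (d00 * d11 - d01 * d01);
  double bv = (d11 * d20 - d01 * d21) * inv;
  double bw = (d00 * d21 - d01 * d20) * inv;
  double bary[3] = {1.0 - bv - bw, bv, bw};
  for (int i = 0; i < 3; ++i)
    o.A[i] = -bary[i] * SA - d * eacc[i];
}

// ---------------------------------------------------------------------------
// Gauss rules on the triangle (barycentric points, weights summing to 1)
// ---------------------------------------------------------------------------

struct QuadRule {
  int n;
  double w[7];
  double b[7][3];
};

static QuadRule get_rule(int npts) {
  QuadRule q;
  if (npts <= 1) {
    q.n = 1; q.w[0] = 1.0;
    q.b[0][0] = q.b[0][1] = q.b[0][2] = 1.0 / 3.0;
  } else if (npts <= 3) {
    q.n = 3;
    for (int i = 0; i < 3; ++i) {
      q.w[i] = 1.0 / 3.0;
      for (int j = 0; j < 3; ++j) q.b[i][j] = (i == j) ? 2.0/3.0 : 1.0/6.0;
    }
  } else if (npts <= 6) { // Strang degree 4
    q.n = 6;
    const double a1 = 0.816847572980459, b1 = 0.091576213509771, w1 = 0.109951743655322;
    const double a2 = 0.108103018168070, b2 = 0.445948490915965, w2 = 0.223381589678011;
    int k = 0;
    for (int i = 0; i < 3; ++i, ++k) {
      q.w[k] = w1;
      for (int j = 0; j < 3; ++j) q.b[k][j] = (i == j) ? a1 : b1;
    }
    for (int i = 0; i < 3; ++i, ++k) {
      q.w[k] = w2;
      for (int j = 0; j < 3; ++j) q.b[k][j] = (i == j) ? a2 : b2;
    }
  } else { // 7-point degree 5
    q.n = 7;
    q.w[0] = 0.225;
    q.b[0][0] = q.b[0][1] = q.b[0][2] = 1.0 / 3.0;
    const double a1 = 0.059715871789770, b1 = 0.470142064105115, w1 = 0.132394152788506;
    const double a2 = 0.797426985353087, b2 = 0.101286507323456, w2 = 0.125939180544827;
    int k = 1;
    for (int i = 0; i < 3; ++i, ++k) {
      q.w[k] = w1;
      for (int j = 0; j < 3; ++j) q.b[k][j] = (i == j) ? a1 : b1;
    }
    for (int i = 0; i < 3; ++i, ++k) {
      q.w[k] = w2;
      for (int j = 0; j < 3; ++j) q.b[k][j] = (i == j) ? a2 : b2;
    }
  }
  return q;
}

// ---------------------------------------------------------------------------
// Adaptive integration of a vector-valued functional over a triangle.
// F signature: void f(const V3& x, double out[K])
// ---------------------------------------------------------------------------

struct QuadOpts {
  QuadRule rule;
  bool adaptive;
  double tol;
  int max_depth;
  double near_gate; // adaptivity engages when dist < near_gate*(size scale)
};

template <int K, class F>
static void rule_eval(const V3& a, const V3& b, const V3& c, F&& f,
                      const QuadRule& q, double out[K]) {
  double area = 0.5 * norm3(cross3(b - a, c - a));
  for (int k = 0; k < K; ++k) out[k] = 0.0;
  double tmp[K];
  for (int i = 0; i < q.n; ++i) {
    V3 x = q.b[i][0] * a + q.b[i][1] * b + q.b[i][2] * c;
    f(x, tmp);
    for (int k = 0; k < K; ++k) out[k] += q.w[i] * tmp[k];
  }
  for (int k = 0; k < K; ++k) out[k] *= area;
}

// Stopping rule: the subdivided estimate s is accepted when
// |s - v0| <= tol * |s| + athr, where athr is an absolute floor seeded at the
// top level with tol * (unsigned sum of the level-1 child estimates) -- this
// bounds the effort on entries that are small through sign cancellation
// (e.g. nearly co-planar double-layer pairs), where a purely relative
// criterion could never be met. athr decays by 4 per level so the total
// absolute error stays O(depth * athr).
template <int K, class F>
static void adapt_rec(const V3& a, const V3& b, const V3& c, const double v0[K],
                      F&& f, const QuadOpts& o, int depth, double athr,
                      double out[K], int& hit_max) {
  V3 ab = 0.5 * (a + b), bc = 0.5 * (b + c), ca = 0.5 * (c + a);
  double v1[K], v2[K], v3[K], v4[K], s[K];
  rule_eval<K>(a, ab, ca, f, o.rule, v1);
  rule_eval<K>(ab, b, bc, f, o.rule, v2);
  rule_eval<K>(ca, bc, c, f, o.rule, v3);
  rule_eval<K>(ab, bc, ca, f, o.rule, v4);
  double diff = 0.0, mag = 0.0, umag = 0.0;
  for (int k = 0; k < K; ++k) {
    s[k] = v1[k] + v2[k] + v3[k] + v4[k];
    diff += std::fabs(s[k] - v0[k]);
    mag += std::fabs(s[k]);
    umag += std::fabs(v1[k]) + std::fabs(v2[k]) + std::fabs(v3[k]) +
      std::fabs(v4[k]);
  }
  if (athr < 0) athr = o.tol * umag; // top level: seed the absolute floor
  if (diff <= o.tol * mag + athr + 1e-300) {
    for (int k = 0; k < K; ++k) out[k] = s[k];
    return;
  }
  if (depth <= 1) {
    for (int k = 0; k < K; ++k) out[k] = s[k];
    ++hit_max;
    return;
  }
  double o1[K], o2[K], o3[K], o4[K];
  double ca4 = athr / 4.0;
  adapt_rec<K>(a, ab, ca, v1, f, o, depth - 1, ca4, o1, hit_max);
  adapt_rec<K>(ab, b, bc, v2, f, o, depth - 1, ca4, o2, hit_max);
  adapt_rec<K>(ca, bc, c, v3, f, o, depth - 1, ca4, o3, hit_max);
  adapt_rec<K>(ab, bc, ca, v4, f, o, depth - 1, ca4, o4, hit_max);
  for (int k = 0; k < K; ++k) out[k] = o1[k] + o2[k] + o3[k] + o4[k];
}

template <int K, class F>
static void integrate_tri(const Tri& t, F&& f, const QuadOpts& o, bool near,
                          double out[K], int& hit_max) {
  double v0[K];
  rule_eval<K>(t.p[0], t.p[1], t.p[2], f, o.rule, v0);
  if (!o.adaptive || !near || o.max_depth <= 0) {
    for (int k = 0; k < K; ++k) out[k] = v0[k];
    return;
  }
  adapt_rec<K>(t.p[0], t.p[1], t.p[2], v0, f, o, o.max_depth, -1.0, out,
               hit_max);
}

static QuadOpts make_opts(int rule, bool adaptive, double tol, int max_depth,
                          double near_gate) {
  QuadOpts o;
  o.rule = get_rule(rule);
  o.adaptive = adaptive;
  o.tol = tol;
  o.max_depth = max_depth;
  o.near_gate = near_gate;
  return o;
}

// ---------------------------------------------------------------------------
// Galerkin single-layer block: S(k,l) = int_{Tk} int_{Tl} G
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_assemble_S(const arma::mat& VA, const arma::imat& FA,
                         const arma::mat& VB, const arma::imat& FB,
                         bool same, int rule, bool adaptive, double tol,
                         int max_depth, double near_gate) {
  std::vector<Tri> TA = build_tris(VA, FA);
  std::vector<Tri> TB = same ? TA : build_tris(VB, FB);
  arma::mat S(TA.size(), TB.size(), arma::fill::zeros);
  QuadOpts o = make_opts(rule, adaptive, tol, max_depth, near_gate);
  int hit = 0;
  for (size_t k = 0; k < TA.size(); ++k) {
    size_t lmax = same ? k + 1 : TB.size();
    for (size_t l = 0; l < lmax; ++l) {
      const Tri& tl = TB[l];
      double dist = norm3(TA[k].cen - tl.cen);
      bool near = dist <= near_gate * (TA[k].diam + tl.diam);
      double val;
      auto f = [&tl](const V3& x, double out[1]) {
        Ana an;
        tri_analytic(tl, x, an);
        out[0] = an.S;
      };
      integrate_tri<1>(TA[k], f, o, near, &val, hit);
      S(k, l) = val / FOURPI;
      if (same && l != k) S(l, k) = S(k, l);
    }
  }
  (void)hit;
  return S;
}

// ---------------------------------------------------------------------------
// Galerkin double-layer block: D(k, b) = int_{Tk in A} int_{SB} psi_k phi_b d_{n'}G
// rows: triangles of A, cols: vertices of B. Principal value on co-planar pairs.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_assemble_D(const arma::mat& VA, const arma::imat& FA,
                         const arma::mat& VB, const arma::imat& FB,
                         bool same, int rule, bool adaptive, double tol,
                         int max_depth, double near_gate) {
  std::vector<Tri> TA = build_tris(VA, FA);
  std::vector<Tri> TB = same ? TA : build_tris(VB, FB);
  arma::mat D(TA.size(), VB.n_rows, arma::fill::zeros);
  QuadOpts o = make_opts(rule, adaptive, tol, max_depth, near_gate);
  int hit = 0;
  for (size_t k = 0; k < TA.size(); ++k) {
    for (size_t l = 0; l < TB.size(); ++l) {
      if (same && l == k) continue; // co-planar: PV contribution is zero
      const Tri& tl = TB[l];
      double dist = norm3(TA[k].cen - tl.cen);
      bool near = dist <= near_gate * (TA[k].diam + tl.diam);
      double val[3];
      auto f = [&tl](const V3& x, double out[3]) {
        Ana an;
        tri_analytic(tl, x, an);
        out[0] = an.A[0]; out[1] = an.A[1]; out[2] = an.A[2];
      };
      integrate_tri<3>(TA[k], f, o, near, val, hit);
      for (int j = 0; j < 3; ++j)
        D(k, FB(l, j) - 1) += val[j] / FOURPI;
    }
  }
  return D;
}

// ---------------------------------------------------------------------------
// Dipole source integrals over a surface:
//   P0(t, d) = int_{Tt} v_d ds          (v = q.(y-r0) / (4 pi ||y-r0||^3))
//   P1(a, d) = int phi_a d_n v_d ds
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_dipole_rhs(const arma::mat& V, const arma::imat& F,
                    const arma::mat& pos, const arma::mat& mom,
                    int rule, bool adaptive, double tol, int max_depth,
                    double near_gate) {
  std::vector<Tri> T = build_tris(V, F);
  const arma::uword nd = pos.n_rows;
  arma::mat P0(T.size(), nd, arma::fill::zeros);
  arma::mat P1(V.n_rows, nd, arma::fill::zeros);
  QuadOpts o = make_opts(rule, adaptive, tol, max_depth, near_gate);
  int hit = 0;
  for (arma::uword d = 0; d < nd; ++d) {
    V3 r0; r0[0] = pos(d, 0); r0[1] = pos(d, 1); r0[2] = pos(d, 2);
    V3 q;  q[0]  = mom(d, 0); q[1]  = mom(d, 1); q[2]  = mom(d, 2);
    for (size_t t = 0; t < T.size(); ++t) {
      const Tri& tr = T[t];
      double dist = norm3(tr.cen - r0);
      // source integrals are cheap (nT x nd pairs) and dominate the accuracy
      // for shallow sources: keep a wide adaptivity gate regardless of the
      // operator gate
      bool near = dist <= std::max(4.0, near_gate) * 2.0 * tr.diam;
      double val[4];
      auto f = [&tr, &r0, &q](const V3& x, double out[4]) {
        V3 R = x - r0;
        double r2 = dot3(R, R);
        double r = std::sqrt(r2);
        double inv3 = 1.0 / (FOURPI * r2 * r);
        double qR = dot3(q, R);
        double v = qR * inv3;
        // grad v = (q - 3 (q.u) u) / (4 pi r^3), u = R/r
        V3 gv = (q - (3.0 * qR / r2) * R) * inv3;
        double dnv = dot3(tr.n, gv);
        // phi_a(x) via affine extension from centroid
        out[0] = v;
        for (int a = 0; a < 3; ++a)
          out[1 + a] = (1.0 / 3.0 + dot3(tr.g[a], x - tr.cen)) * dnv;
      };
      integrate_tri<4>(tr, f, o, near, val, hit);
      P0(t, d) += val[0];
      for (int a = 0; a < 3; ++a) P1(F(t, a) - 1, d) += val[1 + a];
    }
  }
  return List::create(_["P0"] = P0, _["P1"] = P1, _["n_nonconverged"] = hit);
}

// ---------------------------------------------------------------------------
// Ohmic MEG surface integrals: for sensor integration points with directions,
//   M(p, b) = dir_p . int phi_b n'(y) x (r_p - y) / ||r_p - y||^3 ds(y) / (4 pi)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_head2meg(const arma::mat& pts, const arma::mat& dirs,
                       const arma::mat& V, const arma::imat& F,
                       int rule, bool adaptive, double tol, int max_depth,
                       double near_gate) {
  std::vector<Tri> T = build_tris(V, F);
  arma::mat M(pts.n_rows, V.n_rows, arma::fill::zeros);
  QuadOpts o = make_opts(rule, adaptive, tol, max_depth, near_gate);
  int hit = 0;
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    V3 rp; rp[0] = pts(p, 0); rp[1] = pts(p, 1); rp[2] = pts(p, 2);
    V3 dir; dir[0] = dirs(p, 0); dir[1] = dirs(p, 1); dir[2] = dirs(p, 2);
    for (size_t t = 0; t < T.size(); ++t) {
      const Tri& tr = T[t];
      double dist = norm3(tr.cen - rp);
      bool near = dist <= near_gate * 2.0 * tr.diam;
      V3 dxn = cross3(dir, tr.n); // dir.(n x w) = -(dir x n).w ... handled below
      double val[3];
      auto f = [&tr, &rp, &dxn](const V3& x, double out[3]) {
        V3 w = rp - x;
        double r2 = dot3(w, w);
        double inv3 = 1.0 / (r2 * std::sqrt(r2));
        // dir . (n x w) = (dir x n) . w  * (-1)?  Use scalar triple product:
        // dir.(n x w) = det[dir n w] = (dir x n).w
        double kern = dot3(dxn, w) * inv3;
        for (int a = 0; a < 3; ++a)
          out[a] = (1.0 / 3.0 + dot3(tr.g[a], x - tr.cen)) * kern;
      };
      integrate_tri<3>(tr, f, o, near, val, hit);
      for (int a = 0; a < 3; ++a) M(p, F(t, a) - 1) += val[a] / FOURPI;
    }
  }
  return M;
}

// ---------------------------------------------------------------------------
// Point potentials: single/double layer evaluations and winding numbers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_point_potentials(const arma::mat& pts, const arma::mat& V,
                          const arma::imat& F) {
  std::vector<Tri> T = build_tris(V, F);
  arma::mat Spot(pts.n_rows, T.size(), arma::fill::zeros);
  arma::mat Dpot(pts.n_rows, V.n_rows, arma::fill::zeros);
  arma::vec wind(pts.n_rows, arma::fill::zeros);
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    V3 x; x[0] = pts(p, 0); x[1] = pts(p, 1); x[2] = pts(p, 2);
    double sa = 0.0;
    Ana an;
    for (size_t t = 0; t < T.size(); ++t) {
      tri_analytic(T[t], x, an);
      Spot(p, t) = an.S / FOURPI;
      for (int j = 0; j < 3; ++j) Dpot(p, F(t, j) - 1) += an.A[j] / FOURPI;
      sa += an.SA;
    }
    wind(p) = sa / FOURPI;
  }
  return List::create(_["S"] = Spot, _["D"] = Dpot, _["winding"] = wind);
}

// [[Rcpp::export]]
arma::vec cpp_winding(const arma::mat& pts, const arma::mat& V,
                      const arma::imat& F) {
  std::vector<Tri> T = build_tris(V, F);
  arma::vec wind(pts.n_rows, arma::fill::zeros);
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    V3 x; x[0] = pts(p, 0); x[1] = pts(p, 1); x[2] = pts(p, 2);
    double sa = 0.0;
    for (size_t t = 0; t < T.size(); ++t) sa += solid_angle(T[t], x);
    wind(p) = sa / FOURPI;
  }
  return wind;
}

// Analytic integrals of one triangle at a set of points (exposed for tests
// and the internal-potential rows).
// [[Rcpp::export]]
List cpp_triangle_analytic(const arma::mat& pts, const arma::mat& V,
                           const arma::imat& F) {
  std::vector<Tri> T = build_tris(V, F);
  arma::mat Smat(pts.n_rows, T.size());
  arma::cube Amat(pts.n_rows, T.size(), 3);
  arma::mat SAmat(pts.n_rows, T.size());
  Ana an;
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    V3 x; x[0] = pts(p, 0); x[1] = pts(p, 1); x[2] = pts(p, 2);
    for (size_t t = 0; t < T.size(); ++t) {
      tri_analytic(T[t], x, an);
      Smat(p, t) = an.S / FOURPI;
      for (int j = 0; j < 3; ++j) Amat(p, t, j) = an.A[j] / FOURPI;
      SAmat(p, t) = an.SA;
    }
  }
  return List::create(_["single"] = Smat, _["double_linear"] = Amat,
                      _["solid_angle"] = SAmat);
}

// ---------------------------------------------------------------------------
// Closest point on a triangulated surface (Ericson's algorithm per triangle)
// ---------------------------------------------------------------------------

static V3 closest_on_tri(const Tri& t, const V3& p, double bary[3]) {
  const V3 &a = t.p[0], &b = t.p[1], &c = t.p[2];
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { bary[0]=1; bary[1]=0; bary[2]=0; return a; }
  V3 bp = p - b;
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { bary[0]=0; bary[1]=1; bary[2]=0; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return a + v * ab;
  }
  V3 cp = p - c;
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { bary[0]=0; bary[1]=0; bary[2]=1; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
  return a + v * ab + w * ac;
}

// [[Rcpp::export]]
List cpp_closest_point(const arma::mat& pts, const arma::mat& V,
                       const arma::imat& F) {
  std::vector<Tri> T = build_tris(V, F);
  arma::vec dist(pts.n_rows);
  arma::ivec tri(pts.n_rows);
  arma::mat closest(pts.n_rows, 3), bary(pts.n_rows, 3);
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    V3 x; x[0] = pts(p, 0); x[1] = pts(p, 1); x[2] = pts(p, 2);
    double best = INFINITY;
    int bt = -1;
    V3 bc; double bb[3] = {0, 0, 0};
    for (size_t t = 0; t < T.size(); ++t) {
      double ba[3];
      V3 c = closest_on_tri(T[t], x, ba);
      double d2 = dot3(x - c, x - c);
      if (d2 < best - 1e-300 || (bt < 0)) {
        if (d2 < best) {
          best = d2; bt = (int)t; bc = c;
          bb[0] = ba[0]; bb[1] = ba[1]; bb[2] = ba[2];
        }
      }
    }
    dist(p) = std::sqrt(best);
    tri(p) = bt + 1;
    for (int j = 0; j < 3; ++j) { closest(p, j) = bc[j]; bary(p, j) = bb[j]; }
  }
  return List::create(_["dist"] = dist, _["triangle"] = tri,
                      _["closest"] = closest, _["bary"] = bary);
}

// ---------------------------------------------------------------------------
// Incremental 3D convex hull (points in general position; all points on a
// sphere are extreme, so the hull is the spherical triangulation we need).
// Returns 1-based triangles, outward oriented.
// ---------------------------------------------------------------------------

struct HFace { int a, b, c; V3 n; double off; bool alive; };

static V3 getp(const arma::mat& P, int i) {
  V3 v; v[0] = P(i, 0); v[1] = P(i, 1); v[2] = P(i, 2);
  return v;
}

// [[Rcpp::export]]
arma::imat cpp_convex_hull(const arma::mat& P) {
  const int n = (int)P.n_rows;
  if (n < 4) stop("convex hull needs at least 4 points");
  double scale = 0.0;
  for (int i = 0; i < n; ++i) scale = std::max(scale, arma::norm(P.row(i), 2));
  const double eps = 1e-10 * std::max(scale, 1.0);

  // initial tetrahedron
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = norm3(getp(P, i) - getp(P, i0));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= eps) stop("degenerate point set (coincident points)");
  V3 p0 = getp(P, i0), p1 = getp(P, i1);
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    V3 d = cross3(p1 - p0, getp(P, i) - p0);
    double a = norm3(d);
    if (a > best) { best = a; i2 = i; }
  }
  if (best <= eps * eps) stop("degenerate point set (collinear)");
  V3 p2 = getp(P, i2);
  V3 nn = cross3(p1 - p0, p2 - p0);
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double d = std::fabs(dot3(nn, getp(P, i) - p0));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps * norm3(nn)) stop("degenerate point set (coplanar)");

  std::vector<HFace> faces;
  V3 tc = 0.25 * (p0 + p1 + p2 + getp(P, i3));
  auto add_face = [&](int a, int b, int c) {
    HFace f;
    f.a = a; f.b = b; f.c = c;
    V3 pa = getp(P, a);
    f.n = cross3(getp(P, b) - pa, getp(P, c) - pa);
    if (dot3(f.n, tc - pa) > 0) { // ensure outward
      std::swap(f.b, f.c);
      f.n = -f.n;
    }
    f.off = dot3(f.n, pa);
    f.alive = true;
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    V3 p = getp(P, i);
    // visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (dot3(faces[f].n, p) - faces[f].off >
          eps * std::max(1.0, norm3(faces[f].n)))
        vis.push_back((int)f);
    }
    if (vis.empty()) continue; // inside current hull
    // horizon edges: directed edges of visible faces whose reverse is not in a
    // visible face
    std::vector<std::pair<int,int> > edges;
    for (size_t k = 0; k < vis.size(); ++k) {
      const HFace& f = faces[vis[k]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) edges.push_back(std::make_pair(e[j][0], e[j][1]));
    }
    std::vector<std::pair<int,int> > horizon;
    for (size_t k = 0; k < edges.size(); ++k) {
      bool rev = false;
      for (size_t m = 0; m < edges.size(); ++m)
        if (edges[m].first == edges[k].second && edges[m].second == edges[k].first) {
          rev = true; break;
        }
      if (!rev) horizon.push_back(edges[k]);
    }
    for (size_t k = 0; k < vis.size(); ++k) faces[vis[k]].alive = false;
    for (size_t k = 0; k < horizon.size(); ++k) {
      // new face keeps the horizon edge's direction so orientation stays
      // consistent (outward)
      HFace f;
      f.a = horizon[k].first; f.b = horizon[k].second; f.c = i;
      V3 pa = getp(P, f.a);
      f.n = cross3(getp(P, f.b) - pa, getp(P, f.c) - pa);
      f.off = dot3(f.n, pa);
      f.alive = true;
      // safety: orient outward w.r.t. interior centroid
      if (dot3(f.n, tc - pa) > 0) { std::swap(f.b, f.c); f.n = -f.n; f.off = dot3(f.n, pa); }
      faces.push_back(f);
    }
  }

  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) ++nf;
  arma::imat out(nf, 3);
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    out(r, 0) = faces[f].a + 1;
    out(r, 1) = faces[f].b + 1;
    out(r, 2) = faces[f].c + 1;
    ++r;
  }
  return out;
}
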