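// Finite-element kernels: quadratic-displacement / linear-pressure (Taylor-
// Hood) tetrahedra for the incompressible biventricle with Guccione passive
// and sarcomere active stress, and 3-node membrane triangles for the
// constrained-mixture artery wall.  Element residuals are analytic; element
// tangents are forward differences of the residual.  Global assembly,
// constraints and linear solves live on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;

// ---------- quadrature on the reference tetrahedron (4 pt, degree 2) ------
static const double QA = 0.585410196624969;
static const double QB = 0.138196601125011;
static const double QPTS[4][4] = {
  {QA, QB, QB, QB}, {QB, QA, QB, QB}, {QB, QB, QA, QB}, {QB, QB, QB, QA}};
// barycentric (l1..l4); weight 1/4 each (times 6V factor handled via detJ/6)

// Keast 11-point degree-4 rule: exact for the (cubic) Jacobian of a P2
// displacement times a linear pressure test function, so the
// incompressibility constraint is integrated exactly.
static const double KB = 11.0 / 14.0, KC = 1.0 / 14.0;
static const double KD = 0.399403576166799, KE = 0.100596423833201;
static const double QPTS2[11][4] = {
  {0.25, 0.25, 0.25, 0.25},
  {KB, KC, KC, KC}, {KC, KB, KC, KC}, {KC, KC, KB, KC}, {KC, KC, KC, KB},
  {KD, KD, KE, KE}, {KD, KE, KD, KE}, {KD, KE, KE, KD},
  {KE, KD, KD, KE}, {KE, KD, KE, KD}, {KE, KE, KD, KD}};
static const double QW2[11] = {
  -0.0789333333333333,
  0.0457333333333333, 0.0457333333333333, 0.0457333333333333,
  0.0457333333333333,
  0.1493333333333333, 0.1493333333333333, 0.1493333333333333,
  0.1493333333333333, 0.1493333333333333, 0.1493333333333333};

static inline double det3(const double F[3][3]) {
  return F[0][0]*(F[1][1]*F[2][2]-F[1][2]*F[2][1])
       - F[0][1]*(F[1][0]*F[2][2]-F[1][2]*F[2][0])
       + F[0][2]*(F[1][0]*F[2][1]-F[1][1]*F[2][0]);
}
// cofactor matrix (J * F^{-T})
static inline void cof3(const double F[3][3], double C[3][3]) {
  C[0][0] =  F[1][1]*F[2][2]-F[1][2]*F[2][1];
  C[0][1] = -(F[1][0]*F[2][2]-F[1][2]*F[2][0]);
  C[0][2] =  F[1][0]*F[2][1]-F[1][1]*F[2][0];
  C[1][0] = -(F[0][1]*F[2][2]-F[0][2]*F[2][1]);
  C[1][1] =  F[0][0]*F[2][2]-F[0][2]*F[2][0];
  C[1][2] = -(F[0][0]*F[2][1]-F[0][1]*F[2][0]);
  C[2][0] =  F[0][1]*F[1][2]-F[0][2]*F[1][1];
  C[2][1] = -(F[0][0]*F[1][2]-F[0][2]*F[1][0]);
  C[2][2] =  F[0][0]*F[1][1]-F[0][1]*F[1][0];
}

struct GuccMat { double C, bff, bxx, bfx; };
struct ActMat {
  double T0, tr, td, b, ld, a6, a7, Ea, v0, ls0;
  int variant; // 0 printed (active lc < a7), 1 ascending (lc > a7)
};

static inline double f_iso_c(double lc, const ActMat &am) {
  bool active = am.variant == 0 ? (lc < am.a7) : (lc > am.a7);
  if (!active) return 0.0;
  double t = std::tanh(am.a6 * (lc - am.a7));
  return am.T0 * t * t;
}

static inline double f_twitch_c(double t, double ls, const ActMat &am) {
  double tmax = am.b * (ls - am.ld);
  if (t <= 0.0 || t >= tmax) return 0.0;
  double r = std::tanh(t / am.tr), d = std::tanh((tmax - t) / am.td);
  return r * r * d * d;
}

// Guccione second Piola-Kirchhoff stress in global coords.
// R columns: e_f0, e_s0, e_n0.
static mat gucc_pk2(const mat &E, const mat &R, const GuccMat &gm,
                    double *Wout) {
  mat Ef = R.t() * E * R;
  double Q =
    gm.bff * Ef(0, 0) * Ef(0, 0) +
    gm.bxx * (Ef(1, 1) * Ef(1, 1) + Ef(2, 2) * Ef(2, 2) +
              Ef(1, 2) * Ef(1, 2) + Ef(2, 1) * Ef(2, 1)) +
    gm.bfx * (Ef(0, 1) * Ef(0, 1) + Ef(1, 0) * Ef(1, 0) +
              Ef(0, 2) * Ef(0, 2) + Ef(2, 0) * Ef(2, 0));
  double eQ = std::exp(Q);
  if (Wout) *Wout = 0.5 * gm.C * (eQ - 1.0);
  mat dQ(3, 3);
  dQ(0, 0) = 2.0 * gm.bff * Ef(0, 0);
  dQ(1, 1) = 2.0 * gm.bxx * Ef(1, 1);
  dQ(2, 2) = 2.0 * gm.bxx * Ef(2, 2);
  dQ(1, 2) = 2.0 * gm.bxx * Ef(1, 2); dQ(2, 1) = 2.0 * gm.bxx * Ef(2, 1);
  dQ(0, 1) = 2.0 * gm.bfx * Ef(0, 1); dQ(1, 0) = 2.0 * gm.bfx * Ef(1, 0);
  dQ(0, 2) = 2.0 * gm.bfx * Ef(0, 2); dQ(2, 0) = 2.0 * gm.bfx * Ef(2, 0);
  mat Sf = 0.5 * gm.C * eQ * dQ;
  return R * Sf * R.t();
}

// element kinematics helper: gradients of the 10 P2 shape functions
static void p2_grads(const mat &Xv /*4x3*/, double qp[4],
                     mat &gradN /*10x3*/, double &detJ) {
  mat A(3, 3);
  for (int k = 0; k < 3; ++k)
    for (int d = 0; d < 3; ++d) A(d, k) = Xv(k + 1, d) - Xv(0, d);
  detJ = arma::det(A);
  mat Ainv = arma::inv(A);
  // grad lambda_i (i=0..3)
  mat gl(4, 3);
  for (int d = 0; d < 3; ++d) {
    gl(1, d) = Ainv(0, d); gl(2, d) = Ainv(1, d); gl(3, d) = Ainv(2, d);
  }
  // note: grad lambda_{i+1} = row i of A^{-1}?  lambda_{i+1} = xi_i, and
  // grad_x xi = A^{-T} e_i -> components Ainv(i, d)?  A^{-T}(d,i)=Ainv(i,d).
  for (int d = 0; d < 3; ++d) gl(0, d) = -(gl(1, d) + gl(2, d) + gl(3, d));
  const int e1[6] = {0, 0, 0, 1, 1, 2};
  const int e2[6] = {1, 2, 3, 2, 3, 3};
  for (int i = 0; i < 4; ++i)
    for (int d = 0; d < 3; ++d)
      gradN(i, d) = (4.0 * qp[i] - 1.0) * gl(i, d);
  for (int e = 0; e < 6; ++e)
    for (int d = 0; d < 3; ++d)
      gradN(4 + e, d) = 4.0 * (qp[e2[e]] * gl(e1[e], d) +
                               qp[e1[e]] * gl(e2[e], d));
}

struct BvWork {
  // per-element residual at given local state
  // ulocal: 10x3, plocal: 4
  mat Xv;              // 4x3 vertex coords
  mat gradN[4];        // per stress qp 10x3
  double wdet[4];      // detJ/6 * w
  mat gradN2[11];      // per constraint qp 10x3
  double wdet2[11];
  mat R;               // fiber basis columns
  GuccMat gm; ActMat am;
  double lc[4];
  double t_act;
  bool ok;
};

// residual of one element; also outputs energy, int|J-1|, volume, ls per qp
// (plain-array hot path: no heap allocation per quadrature point)
static void bv_elem_residual(BvWork &w, const mat &ulocal, const vec &plocal,
                             mat &ru /*10x3*/, vec &rp /*4*/,
                             double *energy, double *aJm1, double *ls_out) {
  ru.zeros(); rp.zeros();
  w.ok = true;
  double ef0[3] = {w.R(0, 0), w.R(1, 0), w.R(2, 0)};
  double Rm[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Rm[i][j] = w.R(i, j);
  for (int q = 0; q < 4; ++q) {
    const mat &G = w.gradN[q];
    double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    for (int a = 0; a < 10; ++a) {
      const double ua0 = ulocal(a, 0), ua1 = ulocal(a, 1), ua2 = ulocal(a, 2);
      const double g0 = G(a, 0), g1 = G(a, 1), g2 = G(a, 2);
      F[0][0] += ua0 * g0; F[0][1] += ua0 * g1; F[0][2] += ua0 * g2;
      F[1][0] += ua1 * g0; F[1][1] += ua1 * g1; F[1][2] += ua1 * g2;
      F[2][0] += ua2 * g0; F[2][1] += ua2 * g1; F[2][2] += ua2 * g2;
    }
    double J = det3(F);
    if (J <= 1e-6) { w.ok = false; return; }
    // E = (F^T F - I)/2, rotated into the fiber frame: Ef = R^T E R
    double Cg[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Cg[i][j] = F[0][i]*F[0][j] + F[1][i]*F[1][j] + F[2][i]*F[2][j];
    double Eg[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Eg[i][j] = 0.5 * (Cg[i][j] - (i == j ? 1.0 : 0.0));
    double ER[3][3], Ef[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        ER[i][j] = Eg[i][0]*Rm[0][j] + Eg[i][1]*Rm[1][j] + Eg[i][2]*Rm[2][j];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Ef[i][j] = Rm[0][i]*ER[0][j] + Rm[1][i]*ER[1][j] + Rm[2][i]*ER[2][j];
    const GuccMat &gm = w.gm;
    double Q =
      gm.bff * Ef[0][0]*Ef[0][0] +
      gm.bxx * (Ef[1][1]*Ef[1][1] + Ef[2][2]*Ef[2][2] +
                Ef[1][2]*Ef[1][2] + Ef[2][1]*Ef[2][1]) +
      gm.bfx * (Ef[0][1]*Ef[0][1] + Ef[1][0]*Ef[1][0] +
                Ef[0][2]*Ef[0][2] + Ef[2][0]*Ef[2][0]);
    double eQ = std::exp(Q);
    double cf = 0.5 * gm.C * eQ;
    double Sf[3][3];
    Sf[0][0] = cf * 2.0 * gm.bff * Ef[0][0];
    Sf[1][1] = cf * 2.0 * gm.bxx * Ef[1][1];
    Sf[2][2] = cf * 2.0 * gm.bxx * Ef[2][2];
    Sf[1][2] = cf * 2.0 * gm.bxx * Ef[1][2];
    Sf[2][1] = cf * 2.0 * gm.bxx * Ef[2][1];
    Sf[0][1] = cf * 2.0 * gm.bfx * Ef[0][1];
    Sf[1][0] = cf * 2.0 * gm.bfx * Ef[1][0];
    Sf[0][2] = cf * 2.0 * gm.bfx * Ef[0][2];
    Sf[2][0] = cf * 2.0 * gm.bfx * Ef[2][0];
    // S = R Sf R^T ; P = F S
    double RS[3][3], Sg[3][3], P[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        RS[i][j] = Rm[i][0]*Sf[0][j] + Rm[i][1]*Sf[1][j] + Rm[i][2]*Sf[2][j];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Sg[i][j] = RS[i][0]*Rm[j][0] + RS[i][1]*Rm[j][1] + RS[i][2]*Rm[j][2];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        P[i][j] = F[i][0]*Sg[0][j] + F[i][1]*Sg[1][j] + F[i][2]*Sg[2][j];
    // active stress along the deformed fiber direction
    double v[3] = {
      F[0][0]*ef0[0] + F[0][1]*ef0[1] + F[0][2]*ef0[2],
      F[1][0]*ef0[0] + F[1][1]*ef0[1] + F[1][2]*ef0[2],
      F[2][0]*ef0[0] + F[2][1]*ef0[1] + F[2][2]*ef0[2]};
    double lam = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
    double ls = lam * w.am.ls0;
    if (ls_out) ls_out[q] = ls;
    if (w.am.T0 > 0.0) {
      double Pa = (ls / w.am.ls0) * f_iso_c(w.lc[q], w.am) *
        f_twitch_c(w.t_act, ls, w.am) * (ls - w.lc[q]) * w.am.Ea;
      if (Pa != 0.0)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            P[i][j] += Pa * (v[i] / lam) * ef0[j];
    }
    double wq = w.wdet[q];
    for (int a = 0; a < 10; ++a) {
      const double g0 = G(a, 0), g1 = G(a, 1), g2 = G(a, 2);
      ru(a, 0) += wq * (P[0][0]*g0 + P[0][1]*g1 + P[0][2]*g2);
      ru(a, 1) += wq * (P[1][0]*g0 + P[1][1]*g1 + P[1][2]*g2);
      ru(a, 2) += wq * (P[2][0]*g0 + P[2][1]*g1 + P[2][2]*g2);
    }
    if (energy) *energy += wq * 0.5 * gm.C * (eQ - 1.0);
  }
  // incompressibility on the exact degree-4 rule: -p J F^{-T} term in the
  // displacement residual and the -int N (J - 1) constraint residual
  for (int q = 0; q < 11; ++q) {
    const mat &G = w.gradN2[q];
    double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    for (int a = 0; a < 10; ++a) {
      const double ua0 = ulocal(a, 0), ua1 = ulocal(a, 1), ua2 = ulocal(a, 2);
      const double g0 = G(a, 0), g1 = G(a, 1), g2 = G(a, 2);
      F[0][0] += ua0 * g0; F[0][1] += ua0 * g1; F[0][2] += ua0 * g2;
      F[1][0] += ua1 * g0; F[1][1] += ua1 * g1; F[1][2] += ua1 * g2;
      F[2][0] += ua2 * g0; F[2][1] += ua2 * g1; F[2][2] += ua2 * g2;
    }
    double J = det3(F);
    if (J <= 1e-6) { w.ok = false; return; }
    double pq = 0.0;
    for (int vtx = 0; vtx < 4; ++vtx) pq += plocal(vtx) * QPTS2[q][vtx];
    double Cof[3][3];
    cof3(F, Cof);                  // J F^{-T}
    double wq = w.wdet2[q];
    double fac = -pq * wq;
    for (int a = 0; a < 10; ++a) {
      const double g0 = G(a, 0), g1 = G(a, 1), g2 = G(a, 2);
      ru(a, 0) += fac * (Cof[0][0]*g0 + Cof[0][1]*g1 + Cof[0][2]*g2);
      ru(a, 1) += fac * (Cof[1][0]*g0 + Cof[1][1]*g1 + Cof[1][2]*g2);
      ru(a, 2) += fac * (Cof[2][0]*g0 + Cof[2][1]*g1 + Cof[2][2]*g2);
    }
    for (int vtx = 0; vtx < 4; ++vtx)
      rp(vtx) += -wq * QPTS2[q][vtx] * (J - 1.0);
    // |J-1| average uses only the positive-weight points (renormalized on
    // the R side by the positive-weight sum 1.0789333)
    if (aJm1 && wq > 0.0) *aJm1 += wq * std::fabs(J - 1.0);
  }
}

static void bv_setup_work(BvWork &w, const mat &coords, const arma::imat &t10,
                          int e, const mat &fib, const arma::ivec &matid,
                          const std::vector<GuccMat> &gms,
                          const std::vector<ActMat> &ams, const mat &lc,
                          double t_act) {
  w.Xv.set_size(4, 3);
  for (int k = 0; k < 4; ++k)
    for (int d = 0; d < 3; ++d) w.Xv(k, d) = coords(t10(e, k) - 1, d);
  for (int q = 0; q < 4; ++q) {
    double qp[4] = {QPTS[q][0], QPTS[q][1], QPTS[q][2], QPTS[q][3]};
    w.gradN[q].set_size(10, 3);
    double detJ;
    p2_grads(w.Xv, qp, w.gradN[q], detJ);
    w.wdet[q] = detJ / 6.0 * 0.25;
  }
  for (int q = 0; q < 11; ++q) {
    double qp[4] = {QPTS2[q][0], QPTS2[q][1], QPTS2[q][2], QPTS2[q][3]};
    w.gradN2[q].set_size(10, 3);
    double detJ;
    p2_grads(w.Xv, qp, w.gradN2[q], detJ);
    w.wdet2[q] = detJ / 6.0 * QW2[q];
  }
  w.R.set_size(3, 3);
  for (int d = 0; d < 3; ++d) {
    w.R(d, 0) = fib(e, d);
    w.R(d, 1) = fib(e, 3 + d);
    w.R(d, 2) = fib(e, 6 + d);
  }
  int mid = matid(e);
  w.gm = gms[mid]; w.am = ams[mid];
  for (int q = 0; q < 4; ++q) w.lc[q] = lc(e, q);
  w.t_act = t_act;
}

static std::vector<GuccMat> parse_gucc(const NumericMatrix &g) {
  std::vector<GuccMat> out;
  for (int i = 0; i < g.nrow(); ++i)
    out.push_back({g(i, 0), g(i, 1), g(i, 2), g(i, 3)});
  return out;
}
static std::vector<ActMat> parse_act(const NumericMatrix &a) {
  std::vector<ActMat> out;
  for (int i = 0; i < a.nrow(); ++i)
    out.push_back({a(i, 0), a(i, 1), a(i, 2), a(i, 3), a(i, 4), a(i, 5),
                   a(i, 6), a(i, 7), a(i, 8), a(i, 9), (int)a(i, 10)});
  return out;
}

// [[Rcpp::export]]
List bv_residual_cpp(NumericMatrix coords, IntegerMatrix tets10,
                     NumericVector uvec, NumericVector pvec,
                     IntegerVector matid, NumericMatrix gucc,
                     NumericMatrix act, NumericMatrix fib,
                     NumericMatrix lcmat, double t_act) {
  int N = coords.nrow(), M = tets10.nrow();
  mat C(coords.begin(), N, 3);
  arma::imat T(M, 10);
  for (int e = 0; e < M; ++e)
    for (int k = 0; k < 10; ++k) T(e, k) = tets10(e, k);
  mat fibm(fib.begin(), M, 9);
  mat lc(lcmat.begin(), M, 4);
  arma::ivec mid(M);
  for (int e = 0; e < M; ++e) mid(e) = matid[e];
  std::vector<GuccMat> gms = parse_gucc(gucc);
  std::vector<ActMat> ams = parse_act(act);

  vec res_u(3 * N, arma::fill::zeros), res_p(pvec.size(), arma::fill::zeros);
  double energy = 0.0, aJ = 0.0;
  NumericMatrix lsmat(M, 4);
  bool ok = true;
  BvWork w;
  mat ru(10, 3); vec rp(4); mat ulocal(10, 3); vec plocal(4);
  for (int e = 0; e < M && ok; ++e) {
    bv_setup_work(w, C, T, e, fibm, mid, gms, ams, lc, t_act);
    for (int a = 0; a < 10; ++a) {
      int n = T(e, a) - 1;
      for (int d = 0; d < 3; ++d) ulocal(a, d) = uvec[3 * n + d];
    }
    for (int vtx = 0; vtx < 4; ++vtx) plocal(vtx) = pvec[T(e, vtx) - 1];
    double lsq[4];
    bv_elem_residual(w, ulocal, plocal, ru, rp, &energy, &aJ, lsq);
    if (!w.ok) { ok = false; break; }
    for (int a = 0; a < 10; ++a) {
      int n = T(e, a) - 1;
      for (int d = 0; d < 3; ++d) res_u(3 * n + d) += ru(a, d);
    }
    for (int vtx = 0; vtx < 4; ++vtx) res_p(T(e, vtx) - 1) += rp(vtx);
    for (int q = 0; q < 4; ++q) lsmat(e, q) = lsq[q];
  }
  return List::create(_["ok"] = ok, _["res_u"] = res_u, _["res_p"] = res_p,
                      _["energy"] = energy, _["int_absJm1"] = aJ,
                      _["ls"] = lsmat);
}

// [[Rcpp::export]]
List bv_tangent_cpp(NumericMatrix coords, IntegerMatrix tets10,
                    NumericVector uvec, NumericVector pvec,
                    IntegerVector matid, NumericMatrix gucc,
                    NumericMatrix act, NumericMatrix fib,
                    NumericMatrix lcmat, double t_act) {
  int N = coords.nrow(), M = tets10.nrow();
  mat C(coords.begin(), N, 3);
  arma::imat T(M, 10);
  for (int e = 0; e < M; ++e)
    for (int k = 0; k < 10; ++k) T(e, k) = tets10(e, k);
  mat fibm(fib.begin(), M, 9);
  mat lc(lcmat.begin(), M, 4);
  arma::ivec mid(M);
  for (int e = 0; e < M; ++e) mid(e) = matid[e];
  std::vector<GuccMat> gms = parse_gucc(gucc);
  std::vector<ActMat> ams = parse_act(act);

  std::vector<int> ti, tj; std::vector<double> tv;
  ti.reserve(M * 1156); tj.reserve(M * 1156); tv.reserve(M * 1156);
  int np = pvec.size();
  bool ok = true;
  BvWork w;
  mat ru0(10, 3), ru1(10, 3); vec rp0(4), rp1(4);
  mat ulocal(10, 3); vec plocal(4);
  for (int e = 0; e < M && ok; ++e) {
    bv_setup_work(w, C, T, e, fibm, mid, gms, ams, lc, t_act);
    int gdof[34];
    for (int a = 0; a < 10; ++a) {
      int n = T(e, a) - 1;
      for (int d = 0; d < 3; ++d) {
        ulocal(a, d) = uvec[3 * n + d];
        gdof[3 * a + d] = 3 * n + d;            // 0-based u dof
      }
    }
    for (int vtx = 0; vtx < 4; ++vtx) {
      plocal(vtx) = pvec[T(e, vtx) - 1];
      gdof[30 + vtx] = 3 * N + (T(e, vtx) - 1); // 0-based p dof
    }
    bv_elem_residual(w, ulocal, plocal, ru0, rp0, nullptr, nullptr, nullptr);
    if (!w.ok) { ok = false; break; }
    double base = 0.0;
    for (int a = 0; a < 10; ++a)
      for (int d = 0; d < 3; ++d)
        base = std::max(base, std::fabs(ulocal(a, d)));
    double hstep = 1e-6 * (1.0 + base);
    double col[34][34]; // col[j][i]
    for (int jd = 0; jd < 30; ++jd) {
      int a = jd / 3, d = jd % 3;
      double keep = ulocal(a, d);
      ulocal(a, d) = keep + hstep;
      bv_elem_residual(w, ulocal, plocal, ru1, rp1, nullptr, nullptr, nullptr);
      ulocal(a, d) = keep;
      if (!w.ok) { ok = false; break; }
      for (int id = 0; id < 30; ++id)
        col[jd][id] = (ru1(id / 3, id % 3) - ru0(id / 3, id % 3)) / hstep;
      for (int vtx = 0; vtx < 4; ++vtx)
        col[jd][30 + vtx] = (rp1(vtx) - rp0(vtx)) / hstep;
    }
    if (!ok) break;
    // p columns are linear in p: perturb by 1
    for (int vtx = 0; vtx < 4; ++vtx) {
      double keep = plocal(vtx);
      plocal(vtx) = keep + 1.0;
      bv_elem_residual(w, ulocal, plocal, ru1, rp1, nullptr, nullptr, nullptr);
      plocal(vtx) = keep;
      for (int id = 0; id < 30; ++id)
        col[30 + vtx][id] = ru1(id / 3, id % 3) - ru0(id / 3, id % 3);
      for (int vq = 0; vq < 4; ++vq)
        col[30 + vtx][30 + vq] = rp1(vq) - rp0(vq); // zero
    }
    for (int jd = 0; jd < 34; ++jd)
      for (int id = 0; id < 34; ++id) {
        double v = col[jd][id];
        if (v != 0.0) {
          ti.push_back(gdof[id] + 1);
          tj.push_back(gdof[jd] + 1);
          tv.push_back(v);
        }
      }
  }
  return List::create(_["ok"] = ok, _["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tv));
}

// [[Rcpp::export]]
List bv_stress_cpp(NumericMatrix coords, IntegerMatrix tets10,
                   NumericVector uvec, NumericVector pvec,
                   IntegerVector matid, NumericMatrix gucc,
                   NumericMatrix act, NumericMatrix fib,
                   NumericMatrix lcmat, double t_act) {
  int N = coords.nrow(), M = tets10.nrow();
  mat C(coords.begin(), N, 3);
  arma::imat T(M, 10);
  for (int e = 0; e < M; ++e)
    for (int k = 0; k < 10; ++k) T(e, k) = tets10(e, k);
  mat fibm(fib.begin(), M, 9);
  mat lc(lcmat.begin(), M, 4);
  arma::ivec mid(M);
  for (int e = 0; e < M; ++e) mid(e) = matid[e];
  std::vector<GuccMat> gms = parse_gucc(gucc);
  std::vector<ActMat> ams = parse_act(act);

  NumericVector fs(M), vol(M);
  NumericMatrix sig(M, 6);
  BvWork w;
  mat ulocal(10, 3); vec plocal(4);
  for (int e = 0; e < M; ++e) {
    bv_setup_work(w, C, T, e, fibm, mid, gms, ams, lc, t_act);
    for (int a = 0; a < 10; ++a) {
      int n = T(e, a) - 1;
      for (int d = 0; d < 3; ++d) ulocal(a, d) = uvec[3 * n + d];
    }
    for (int vtx = 0; vtx < 4; ++vtx) plocal(vtx) = pvec[T(e, vtx) - 1];
    vec ef0 = w.R.col(0);
    double fsum = 0.0, vsum = 0.0; arma::vec ssum(6, arma::fill::zeros);
    for (int q = 0; q < 4; ++q) {
      const mat &G = w.gradN[q];
      mat F(3, 3, arma::fill::eye);
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            F(i, j) += ulocal(a, i) * G(a, j);
      double J = arma::det(F);
      mat E = 0.5 * (F.t() * F - arma::eye(3, 3));
      mat S = gucc_pk2(E, w.R, w.gm, nullptr);
      mat P = F * S;
      vec v = F * ef0;
      double lam = arma::norm(v);
      double ls = lam * w.am.ls0;
      if (w.am.T0 > 0.0) {
        double Pa = (ls / w.am.ls0) * f_iso_c(w.lc[q], w.am) *
          f_twitch_c(w.t_act, ls, w.am) * (ls - w.lc[q]) * w.am.Ea;
        if (Pa != 0.0) P += Pa * ((v / lam) * ef0.t());
      }
      double pq = 0.0;
      for (int vtx = 0; vtx < 4; ++vtx) pq += plocal(vtx) * QPTS[q][vtx];
      P -= pq * J * arma::inv(F).t();
      mat sigma = (P * F.t()) / J;
      vec ef = v / lam;
      double sf = arma::as_scalar(ef.t() * sigma * ef);
      double wq = w.wdet[q];
      fsum += wq * sf; vsum += wq;
      ssum(0) += wq * sigma(0, 0); ssum(1) += wq * sigma(1, 1);
      ssum(2) += wq * sigma(2, 2); ssum(3) += wq * sigma(0, 1);
      ssum(4) += wq * sigma(0, 2); ssum(5) += wq * sigma(1, 2);
    }
    fs[e] = fsum / vsum; vol[e] = vsum;
    for (int k = 0; k < 6; ++k) sig(e, k) = ssum(k) / vsum;
  }
  return List::create(_["fiber_stress"] = fs, _["vol"] = vol,
                      _["sigma"] = sig);
}

// [[Rcpp::export]]
List bv_weights_cpp(NumericMatrix coords, IntegerMatrix tets10) {
  int N = coords.nrow(), M = tets10.nrow();
  mat C(coords.begin(), N, 3);
  vec m0(3 * N, arma::fill::zeros); // per u-dof is wasteful; per node:
  NumericVector w0(N);
  NumericMatrix w1(N, 3);
  for (int e = 0; e < M; ++e) {
    mat Xv(4, 3);
    for (int k = 0; k < 4; ++k)
      for (int d = 0; d < 3; ++d) Xv(k, d) = C(tets10(e, k) - 1, d);
    mat A(3, 3);
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d) A(d, k) = Xv(k + 1, d) - Xv(0, d);
    double detJ = arma::det(A);
    for (int q = 0; q < 4; ++q) {
      double wq = detJ / 6.0 * 0.25;
      double Xq[3] = {0, 0, 0};
      for (int k = 0; k < 4; ++k)
        for (int d = 0; d < 3; ++d) Xq[d] += QPTS[q][k] * Xv(k, d);
      // P2 shape values at qp
      double Nv[10];
      for (int k = 0; k < 4; ++k)
        Nv[k] = QPTS[q][k] * (2.0 * QPTS[q][k] - 1.0);
      const int e1[6] = {0, 0, 0, 1, 1, 2};
      const int e2[6] = {1, 2, 3, 2, 3, 3};
      for (int ed = 0; ed < 6; ++ed)
        Nv[4 + ed] = 4.0 * QPTS[q][e1[ed]] * QPTS[q][e2[ed]];
      for (int a = 0; a < 10; ++a) {
        int n = tets10(e, a) - 1;
        w0[n] += wq * Nv[a];
        for (int d = 0; d < 3; ++d) w1(n, d) += wq * Nv[a] * Xq[d];
      }
    }
  }
  return List::create(_["w0"] = w0, _["w1"] = w1);
}

// gradient of (1/6) sum det(x1,x2,x3) over oriented (sub)triangles
// [[Rcpp::export]]
NumericMatrix cav_grad_cpp(NumericMatrix x, IntegerMatrix sub) {
  int N = x.nrow(), K = sub.nrow();
  NumericMatrix g(N, 3);
  for (int k = 0; k < K; ++k) {
    int a = sub(k, 0) - 1, b = sub(k, 1) - 1, c = sub(k, 2) - 1;
    double x1[3] = {x(a,0), x(a,1), x(a,2)};
    double x2[3] = {x(b,0), x(b,1), x(b,2)};
    double x3[3] = {x(c,0), x(c,1), x(c,2)};
    g(a,0) += (x2[1]*x3[2] - x2[2]*x3[1]) / 6.0;
    g(a,1) += (x2[2]*x3[0] - x2[0]*x3[2]) / 6.0;
    g(a,2) += (x2[0]*x3[1] - x2[1]*x3[0]) / 6.0;
    g(b,0) += (x3[1]*x1[2] - x3[2]*x1[1]) / 6.0;
    g(b,1) += (x3[2]*x1[0] - x3[0]*x1[2]) / 6.0;
    g(b,2) += (x3[0]*x1[1] - x3[1]*x1[0]) / 6.0;
    g(c,0) += (x1[1]*x2[2] - x1[2]*x2[1]) / 6.0;
    g(c,1) += (x1[2]*x2[0] - x1[0]*x2[2]) / 6.0;
    g(c,2) += (x1[0]*x2[1] - x1[1]*x2[0]) / 6.0;
  }
  return g;
}

// ------------------------------ membrane ---------------------------------

struct MembMat {
  double ke;        // M_e * c1
  double kc[4];     // M_i * c2 per family
  double c3;
  double km;        // M_m * c4
  double c5;
  double dir[5][2]; // family unit vectors in the local frame
};

// in-plane PK2 from C2 (2x2), condensed incompressible membrane
static void memb_pk2(const double C2[3], const MembMat &mm, double S[3],
                     double *Wout) {
  // C2 stored as (C11, C22, C12)
  double det = C2[0] * C2[1] - C2[2] * C2[2];
  double idet = 1.0 / det;
  // elastin
  double W = 0.5 * mm.ke * (C2[0] + C2[1] + idet - 3.0);
  // S_e = ke (I - C2inv/det)
  double i11 = C2[1] * idet, i22 = C2[0] * idet, i12 = -C2[2] * idet;
  S[0] = mm.ke * (1.0 - i11 * idet);
  S[1] = mm.ke * (1.0 - i22 * idet);
  S[2] = mm.ke * (-i12 * idet);
  for (int f = 0; f < 5; ++f) {
    double kf = f < 4 ? mm.kc[f] : mm.km;
    double cf = f < 4 ? mm.c3 : mm.c5;
    if (kf == 0.0) continue;
    double e1 = mm.dir[f][0], e2 = mm.dir[f][1];
    double lam2 = C2[0] * e1 * e1 + 2.0 * C2[2] * e1 * e2 + C2[1] * e2 * e2;
    double g = lam2 - 1.0;
    double q = cf * g * g;
    if (q > 60.0) q = 60.0;   // overflow guard far outside physiologic range
    double ex = std::exp(q);
    W += kf / (4.0 * cf) * (ex - 1.0);
    double dW = 0.5 * kf * g * ex; // dW/dlam2
    S[0] += 2.0 * dW * e1 * e1;
    S[1] += 2.0 * dW * e2 * e2;
    S[2] += 2.0 * dW * e1 * e2;
  }
  if (Wout) *Wout = W;
}

struct MembWork {
  // per element: reference inverse edge matrix rows, area*h
  double r1[2], r2[2], Ah;
  int n1, n2, n3; // 0-based nodes
};

static void memb_elem_residual(const MembWork &w, const double x1[3],
                               const double x2[3], const double x3[3],
                               const MembMat &mm, double r[9],
                               double *Wout, double C2out[3]) {
  double d1[3], d2[3];
  for (int d = 0; d < 3; ++d) { d1[d] = x2[d] - x1[d]; d2[d] = x3[d] - x1[d]; }
  // F_s = d1 (x) r1 + d2 (x) r2  (3x2)
  double F[3][2];
  for (int d = 0; d < 3; ++d) {
    F[d][0] = d1[d] * w.r1[0] + d2[d] * w.r2[0];
    F[d][1] = d1[d] * w.r1[1] + d2[d] * w.r2[1];
  }
  double C2[3] = {
    F[0][0]*F[0][0] + F[1][0]*F[1][0] + F[2][0]*F[2][0],
    F[0][1]*F[0][1] + F[1][1]*F[1][1] + F[2][1]*F[2][1],
    F[0][0]*F[0][1] + F[1][0]*F[1][1] + F[2][0]*F[2][1]};
  double S[3], W;
  memb_pk2(C2, mm, S, &W);
  if (Wout) *Wout = w.Ah * W;
  if (C2out) { C2out[0] = C2[0]; C2out[1] = C2[1]; C2out[2] = C2[2]; }
  // P = F_s S (3x2); r_a = Ah * P g_a, g_2 = r1, g_3 = r2, g_1 = -(r1+r2)
  double P[3][2];
  for (int d = 0; d < 3; ++d) {
    P[d][0] = F[d][0] * S[0] + F[d][1] * S[2];
    P[d][1] = F[d][0] * S[2] + F[d][1] * S[1];
  }
  for (int d = 0; d < 3; ++d) {
    double ra2 = w.Ah * (P[d][0] * w.r1[0] + P[d][1] * w.r1[1]);
    double ra3 = w.Ah * (P[d][0] * w.r2[0] + P[d][1] * w.r2[1]);
    r[3 + d] = ra2; r[6 + d] = ra3; r[d] = -(ra2 + ra3);
  }
}

static MembMat parse_memb(const NumericVector &mp, const NumericMatrix &dirs) {
  MembMat mm;
  mm.ke = mp[0];
  for (int f = 0; f < 4; ++f) mm.kc[f] = mp[1 + f];
  mm.c3 = mp[5]; mm.km = mp[6]; mm.c5 = mp[7];
  for (int f = 0; f < 5; ++f) {
    mm.dir[f][0] = dirs(0, f); mm.dir[f][1] = dirs(1, f);
  }
  return mm;
}

// mp: ke, kc1..kc4, c3, km, c5 ; dirs: 2x5 local family vectors
// r1r2: M x 4 (r1x, r1y, r2x, r2y); Ah: M
// [[Rcpp::export]]
List memb_residual_cpp(NumericMatrix nodes, IntegerMatrix tris,
                       NumericVector uvec, NumericMatrix r1r2,
                       NumericVector Ah, NumericVector mp,
                       NumericMatrix dirs) {
  int N = nodes.nrow(), M = tris.nrow();
  MembMat mm = parse_memb(mp, dirs);
  vec res(3 * N, arma::fill::zeros);
  double energy = 0.0;
  double x[3][3]; double r[9];
  for (int e = 0; e < M; ++e) {
    MembWork w;
    w.r1[0] = r1r2(e, 0); w.r1[1] = r1r2(e, 1);
    w.r2[0] = r1r2(e, 2); w.r2[1] = r1r2(e, 3);
    w.Ah = Ah[e];
    int nn[3] = {tris(e, 0) - 1, tris(e, 1) - 1, tris(e, 2) - 1};
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d)
        x[k][d] = nodes(nn[k], d) + uvec[3 * nn[k] + d];
    double W;
    memb_elem_residual(w, x[0], x[1], x[2], mm, r, &W, nullptr);
    energy += W;
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d)
        res(3 * nn[k] + d) += r[3 * k + d];
  }
  return List::create(_["res"] = res, _["energy"] = energy);
}

// [[Rcpp::export]]
List memb_tangent_cpp(NumericMatrix nodes, IntegerMatrix tris,
                      NumericVector uvec, NumericMatrix r1r2,
                      NumericVector Ah, NumericVector mp,
                      NumericMatrix dirs) {
  int N = nodes.nrow(), M = tris.nrow();
  MembMat mm = parse_memb(mp, dirs);
  std::vector<int> ti, tj; std::vector<double> tv;
  ti.reserve(M * 81); tj.reserve(M * 81); tv.reserve(M * 81);
  double x[3][3]; double r0[9], r1v[9];
  for (int e = 0; e < M; ++e) {
    MembWork w;
    w.r1[0] = r1r2(e, 0); w.r1[1] = r1r2(e, 1);
    w.r2[0] = r1r2(e, 2); w.r2[1] = r1r2(e, 3);
    w.Ah = Ah[e];
    int nn[3] = {tris(e, 0) - 1, tris(e, 1) - 1, tris(e, 2) - 1};
    double base = 0.0;
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d) {
        x[k][d] = nodes(nn[k], d) + uvec[3 * nn[k] + d];
        base = std::max(base, std::fabs(x[k][d]));
      }
    double hstep = 1e-5 * (1.0 + base);
    memb_elem_residual(w, x[0], x[1], x[2], mm, r0, nullptr, nullptr);
    int gd[9];
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d) gd[3 * k + d] = 3 * nn[k] + d;
    double rm[9];
    for (int jd = 0; jd < 9; ++jd) {
      int k = jd / 3, d = jd % 3;
      double keep = x[k][d];
      x[k][d] = keep + hstep;
      memb_elem_residual(w, x[0], x[1], x[2], mm, r1v, nullptr, nullptr);
      x[k][d] = keep - hstep;
      memb_elem_residual(w, x[0], x[1], x[2], mm, rm, nullptr, nullptr);
      x[k][d] = keep;
      for (int id = 0; id < 9; ++id) {
        double v = (r1v[id] - rm[id]) / (2.0 * hstep);
        if (v != 0.0) {
          ti.push_back(gd[id] + 1);
          tj.push_back(gd[jd] + 1);
          tv.push_back(v);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tv));
}

// per-element in-plane Cauchy stress invariants and von Mises
// [[Rcpp::export]]
List memb_stress_cpp(NumericMatrix nodes, IntegerMatrix tris,
                     NumericVector uvec, NumericMatrix r1r2,
                     NumericVector Ah, NumericVector mp,
                     NumericMatrix dirs) {
  int M = tris.nrow();
  MembMat mm = parse_memb(mp, dirs);
  NumericVector vm(M), s1(M), s2(M);
  double x[3][3]; double r[9];
  for (int e = 0; e < M; ++e) {
    MembWork w;
    w.r1[0] = r1r2(e, 0); w.r1[1] = r1r2(e, 1);
    w.r2[0] = r1r2(e, 2); w.r2[1] = r1r2(e, 3);
    w.Ah = Ah[e];
    int nn[3] = {tris(e, 0) - 1, tris(e, 1) - 1, tris(e, 2) - 1};
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d)
        x[k][d] = nodes(nn[k], d) + uvec[3 * nn[k] + d];
    // recompute F_s, S, sigma = F_s S F_s^T (3x3 rank 2)
    double d1[3], d2[3];
    for (int d = 0; d < 3; ++d) { d1[d] = x[1][d] - x[0][d]; d2[d] = x[2][d] - x[0][d]; }
    double F[3][2];
    for (int d = 0; d < 3; ++d) {
      F[d][0] = d1[d] * w.r1[0] + d2[d] * w.r2[0];
      F[d][1] = d1[d] * w.r1[1] + d2[d] * w.r2[1];
    }
    double C2[3] = {
      F[0][0]*F[0][0] + F[1][0]*F[1][0] + F[2][0]*F[2][0],
      F[0][1]*F[0][1] + F[1][1]*F[1][1] + F[2][1]*F[2][1],
      F[0][0]*F[0][1] + F[1][0]*F[1][1] + F[2][0]*F[2][1]};
    double S[3];
    memb_pk2(C2, mm, S, nullptr);
    // sigma in-plane invariants via 2x2 matrix C2*S-ish: principal values of
    // F S F^T equal eigenvalues of (S C2) (similar matrices)
    double A11 = S[0] * C2[0] + S[2] * C2[2];
    double A12 = S[0] * C2[2] + S[2] * C2[1];
    double A21 = S[2] * C2[0] + S[1] * C2[2];
    double A22 = S[2] * C2[2] + S[1] * C2[1];
    double tr = A11 + A22, det = A11 * A22 - A12 * A21;
    double disc = std::sqrt(std::max(0.0, tr * tr / 4.0 - det));
    double p1 = tr / 2.0 + disc, p2 = tr / 2.0 - disc;
    s1[e] = p1; s2[e] = p2;
    vm[e] = std::sqrt(std::max(0.0, p1 * p1 + p2 * p2 - p1 * p2));
  }
  return List::create(_["vm"] = vm, _["s1"] = s1, _["s2"] = s2);
}
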