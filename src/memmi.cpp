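#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3x3 helpers ---------------------------------------------------------------

static inline double det3(const double* m) {
  return m[0] * (m[4] * m[8] - m[5] * m[7])
       - m[1] * (m[3] * m[8] - m[5] * m[6])
       + m[2] * (m[3] * m[7] - m[4] * m[6]);
}

static inline bool inv3(const double* m, double* out) {
  double d = det3(m);
  if (d <= 0.0) return false;
  double id = 1.0 / d;
  out[0] =  (m[4] * m[8] - m[5] * m[7]) * id;
  out[1] = -(m[1] * m[8] - m[2] * m[7]) * id;
  out[2] =  (m[1] * m[5] - m[2] * m[4]) * id;
  out[3] = -(m[3] * m[8] - m[5] * m[6]) * id;
  out[4] =  (m[0] * m[8] - m[2] * m[6]) * id;
  out[5] = -(m[0] * m[5] - m[2] * m[3]) * id;
  out[6] =  (m[3] * m[7] - m[4] * m[6]) * id;
  out[7] = -(m[0] * m[7] - m[1] * m[6]) * id;
  out[8] =  (m[0] * m[4] - m[1] * m[3]) * id;
  return true;
}

static const double TWO_PI = 6.283185307179586;

// weight-scaled overlap of two 3-D Gaussians:
// w1*w2 * N(mu1 - mu2; 0, C1 + C2)
// [[Rcpp::export]]
double cpp_pair_overlap(double w1, NumericVector mu1, NumericMatrix C1,
                        double w2, NumericVector mu2, NumericMatrix C2) {
  double S[9], Si[9];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      S[3 * a + b] = C1(a, b) + C2(a, b);
  double d = det3(S);
  if (d <= 0.0 || !inv3(S, Si)) stop("covariance sum is not positive-definite");
  double dx[3] = {mu1[0] - mu2[0], mu1[1] - mu2[1], mu1[2] - mu2[2]};
  double q = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      q += dx[a] * Si[3 * a + b] * dx[b];
  double nc = 1.0 / std::sqrt(TWO_PI * TWO_PI * TWO_PI * d);
  return w1 * w2 * nc * std::exp(-0.5 * q);
}

// overlap vector ov_MD: model atoms are isotropic Gaussians; per data
// component the combined covariance (Sigma_i + sigma^2 I) is pre-inverted in
// R and passed as dinv (K x 9, row-major) with normalisation dnc (K).
// nl: list of 1-based model-atom index vectors, one per data component.
// [[Rcpp::export]]
NumericVector cpp_overlaps(NumericMatrix coords, NumericVector atomw,
                           NumericMatrix dmu, NumericMatrix dinv,
                           NumericVector dnc, NumericVector dw, List nl) {
  int K = dmu.nrow();
  NumericVector ov(K);
  for (int i = 0; i < K; ++i) {
    IntegerVector idx = nl[i];
    double mi0 = dmu(i, 0), mi1 = dmu(i, 1), mi2 = dmu(i, 2);
    const double* Si = &dinv(i, 0);
    // NumericMatrix is column-major: reconstruct row i of dinv
    double S[9];
    for (int c = 0; c < 9; ++c) S[c] = dinv(i, c);
    double acc = 0.0;
    for (int t = 0; t < idx.size(); ++t) {
      int j = idx[t] - 1;
      double d0 = coords(j, 0) - mi0;
      double d1 = coords(j, 1) - mi1;
      double d2 = coords(j, 2) - mi2;
      double q = d0 * (S[0] * d0 + S[1] * d1 + S[2] * d2)
               + d1 * (S[3] * d0 + S[4] * d1 + S[5] * d2)
               + d2 * (S[6] * d0 + S[7] * d1 + S[8] * d2);
      acc += atomw[j] * std::exp(-0.5 * q);
    }
    ov[i] = dw[i] * dnc[i] * acc;
    (void)Si;
  }
  return ov;
}

// G_j = sum_i pref_i * d ov_i / d x_j  (used for restraint forces and for
// single-component overlap gradients via an indicator pref).
// [[Rcpp::export]]
NumericMatrix cpp_overlap_weighted_grad(NumericMatrix coords, NumericVector atomw,
                                        NumericMatrix dmu, NumericMatrix dinv,
                                        NumericVector dnc, NumericVector dw,
                                        List nl, NumericVector pref) {
  int N = coords.nrow(), K = dmu.nrow();
  NumericMatrix G(N, 3);
  for (int i = 0; i < K; ++i) {
    double p = pref[i];
    if (p == 0.0) continue;
    IntegerVector idx = nl[i];
    double S[9];
    for (int c = 0; c < 9; ++c) S[c] = dinv(i, c);
    double mi0 = dmu(i, 0), mi1 = dmu(i, 1), mi2 = dmu(i, 2);
    double wnc = dw[i] * dnc[i];
    for (int t = 0; t < idx.size(); ++t) {
      int j = idx[t] - 1;
      double d0 = coords(j, 0) - mi0;
      double d1 = coords(j, 1) - mi1;
      double d2 = coords(j, 2) - mi2;
      double g0 = S[0] * d0 + S[1] * d1 + S[2] * d2;
      double g1 = S[3] * d0 + S[4] * d1 + S[5] * d2;
      double g2 = S[6] * d0 + S[7] * d1 + S[8] * d2;
      double q = d0 * g0 + d1 * g1 + d2 * g2;
      double ovij = wnc * atomw[j] * std::exp(-0.5 * q);
      G(j, 0) += -p * ovij * g0;
      G(j, 1) += -p * ovij * g1;
      G(j, 2) += -p * ovij * g2;
    }
  }
  return G;
}

// all pairwise weight-scaled overlaps between two general mixtures
// (K1 x K2 matrix); covariances passed as 3x3xK arrays flattened col-major.
// [[Rcpp::export]]
NumericMatrix cpp_cross_overlaps(NumericVector w1, NumericMatrix mu1,
                                 NumericVector cov1, NumericVector w2,
                                 NumericMatrix mu2, NumericVector cov2) {
  int K1 = mu1.nrow(), K2 = mu2.nrow();
  NumericMatrix out(K1, K2);
  for (int i = 0; i < K1; ++i) {
    for (int j = 0; j < K2; ++j) {
      double S[9], Si[9];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          S[3 * a + b] = cov1[9 * i + 3 * b + a] + cov2[9 * j + 3 * b + a];
      double d = det3(S);
      if (d <= 0.0 || !inv3(S, Si))
        stop("covariance sum is not positive-definite");
      double dx[3] = {mu1(i, 0) - mu2(j, 0), mu1(i, 1) - mu2(j, 1),
                      mu1(i, 2) - mu2(j, 2)};
      double q = 0.0;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          q += dx[a] * Si[3 * a + b] * dx[b];
      out(i, j) = w1[i] * w2[j] *
        std::exp(-0.5 * q) / std::sqrt(TWO_PI * TWO_PI * TWO_PI * d);
    }
  }
  return out;
}

// neighbor sets: atom j belongs to data component i iff the pair overlap
// exceeds cutoff * ovDD_i. Returns 1-based index vectors.
// [[Rcpp::export]]
List cpp_nl_build(NumericMatrix coords, NumericVector atomw,
                  NumericMatrix dmu, NumericMatrix dinv, NumericVector dnc,
                  NumericVector dw, NumericVector ovDD, double cutoff) {
  int N = coords.nrow(), K = dmu.nrow();
  List out(K);
  for (int i = 0; i < K; ++i) {
    double S[9];
    for (int c = 0; c < 9; ++c) S[c] = dinv(i, c);
    double mi0 = dmu(i, 0), mi1 = dmu(i, 1), mi2 = dmu(i, 2);
    double thr = cutoff * ovDD[i];
    double wnc = dw[i] * dnc[i];
    std::vector<int> idx;
    for (int j = 0; j < N; ++j) {
      double d0 = coords(j, 0) - mi0;
      double d1 = coords(j, 1) - mi1;
      double d2 = coords(j, 2) - mi2;
      double q = d0 * (S[0] * d0 + S[1] * d1 + S[2] * d2)
               + d1 * (S[3] * d0 + S[4] * d1 + S[5] * d2)
               + d2 * (S[6] * d0 + S[7] * d1 + S[8] * d2);
      if (wnc * atomw[j] * std::exp(-0.5 * q) > thr) idx.push_back(j + 1);
    }
    out[i] = wrap(idx);
  }
  return out;
}

// toy force field -----------------------------------------------------------

static inline double wrap_pi(double x) {
  // map to [-pi, pi)
  return x - TWO_PI * std::floor((x + M_PI) / TWO_PI);
}

static void dihedral_geom(const NumericMatrix& X, int i, int j, int k, int l,
                          double& phi, double dphi[4][3]) {
  double b1[3], b2[3], b3[3];
  for (int c = 0; c < 3; ++c) {
    b1[c] = X(j, c) - X(i, c);
    b2[c] = X(k, c) - X(j, c);
    b3[c] = X(l, c) - X(k, c);
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                  b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                  b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double n1sq = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
  double n2sq = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
  double b2n = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  if (n1sq < 1e-14 || n2sq < 1e-14 || b2n < 1e-10)
    stop("degenerate dihedral geometry (collinear atoms)");
  double m1[3] = {n1[1] * n2[2] - n1[2] * n2[1],
                  n1[2] * n2[0] - n1[0] * n2[2],
                  n1[0] * n2[1] - n1[1] * n2[0]};
  double y = (m1[0] * b2[0] + m1[1] * b2[1] + m1[2] * b2[2]) / b2n;
  double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  phi = std::atan2(y, x);
  double f1 = -b2n / n1sq, f4 = b2n / n2sq;
  double c12 = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (b2n * b2n);
  double c32 = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (b2n * b2n);
  for (int c = 0; c < 3; ++c) {
    double g1 = f1 * n1[c];
    double g4 = f4 * n2[c];
    dphi[0][c] = g1;
    dphi[3][c] = g4;
    dphi[1][c] = -(1.0 + c12) * g1 + c32 * g4;
    dphi[2][c] = c12 * g1 - (1.0 + c32) * g4;
  }
}

// bonded + repulsive energy and forces for the bead model.
// bonds: (i, j, r0, k); angles: (i, j, k, th0, kth)
// dihedrals: (i, j, k, l, kd, mult, phase, type) type 1 = cosine
//   U = kd (1 + cos(mult*phi - phase)); type 2 = harmonic U = kd/2 wrap(phi-phase)^2
// pairs: (i, j) non-excluded repulsive WCA pairs with parameters eps, sig.
// posK/posRef: per-bead harmonic position restraints (posK 0 = free).
// All indices 1-based.
// [[Rcpp::export]]
List cpp_ff(NumericMatrix coords, NumericMatrix bonds, NumericMatrix angles,
            NumericMatrix dihedrals, IntegerMatrix pairs, double eps, double sig,
            NumericVector posK, NumericMatrix posRef) {
  int N = coords.nrow();
  NumericMatrix F(N, 3);
  double E = 0.0;

  for (int i = 0; i < N; ++i) {
    if (posK[i] <= 0.0) continue;
    for (int c = 0; c < 3; ++c) {
      double d = coords(i, c) - posRef(i, c);
      E += 0.5 * posK[i] * d * d;
      F(i, c) -= posK[i] * d;
    }
  }

  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
    double r0 = bonds(b, 2), k = bonds(b, 3);
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) { d[c] = coords(j, c) - coords(i, c); r2 += d[c] * d[c]; }
    double r = std::sqrt(r2);
    double dr = r - r0;
    E += 0.5 * k * dr * dr;
    double fpr = -k * dr / r;
    for (int c = 0; c < 3; ++c) {
      F(j, c) += fpr * d[c];
      F(i, c) -= fpr * d[c];
    }
  }

  for (int a = 0; a < angles.nrow(); ++a) {
    int i = (int)angles(a, 0) - 1, j = (int)angles(a, 1) - 1, k = (int)angles(a, 2) - 1;
    double th0 = angles(a, 3), kth = angles(a, 4);
    double rij[3], rkj[3];
    double nij2 = 0, nkj2 = 0, dot = 0;
    for (int c = 0; c < 3; ++c) {
      rij[c] = coords(i, c) - coords(j, c);
      rkj[c] = coords(k, c) - coords(j, c);
      nij2 += rij[c] * rij[c];
      nkj2 += rkj[c] * rkj[c];
      dot += rij[c] * rkj[c];
    }
    double nij = std::sqrt(nij2), nkj = std::sqrt(nkj2);
    double ct = dot / (nij * nkj);
    ct = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, ct));
    double th = std::acos(ct);
    double dth = th - th0;
    E += 0.5 * kth * dth * dth;
    double st = std::sqrt(1.0 - ct * ct);
    // F_i = -dU/dr_i = (kth * dth / sin) * dcos/dr_i  (theta = acos(ct))
    double pref = kth * dth / st;
    for (int c = 0; c < 3; ++c) {
      double dcdi = (rkj[c] / (nij * nkj)) - ct * rij[c] / nij2;
      double dcdk = (rij[c] / (nij * nkj)) - ct * rkj[c] / nkj2;
      // dU/dri = kth*dth * dth/dcos * dcos/dri ; dth/dcos = -1/sin
      double fi = pref * dcdi;   // = -dU/dri
      double fk = pref * dcdk;
      F(i, c) += fi;
      F(k, c) += fk;
      F(j, c) -= fi + fk;
    }
  }

  for (int d0 = 0; d0 < dihedrals.nrow(); ++d0) {
    int i = (int)dihedrals(d0, 0) - 1, j = (int)dihedrals(d0, 1) - 1;
    int k = (int)dihedrals(d0, 2) - 1, l = (int)dihedrals(d0, 3) - 1;
    double kd = dihedrals(d0, 4), mult = dihedrals(d0, 5), phase = dihedrals(d0, 6);
    int type = (int)dihedrals(d0, 7);
    double phi, dphi[4][3];
    dihedral_geom(coords, i, j, k, l, phi, dphi);
    double dU;
    if (type == 1) {
      E += kd * (1.0 + std::cos(mult * phi - phase));
      dU = -kd * mult * std::sin(mult * phi - phase);
    } else {
      double dd = wrap_pi(phi - phase);
      E += 0.5 * kd * dd * dd;
      dU = kd * dd;
    }
    int at[4] = {i, j, k, l};
    for (int t = 0; t < 4; ++t)
      for (int c = 0; c < 3; ++c)
        F(at[t], c) -= dU * dphi[t][c];
  }

  double cut = std::pow(2.0, 1.0 / 6.0) * sig;
  double cut2 = cut * cut;
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) { d[c] = coords(j, c) - coords(i, c); r2 += d[c] * d[c]; }
    if (r2 >= cut2) continue;
    double s2 = sig * sig / r2;
    double s6 = s2 * s2 * s2;
    double s12 = s6 * s6;
    E += 4.0 * eps * (s12 - s6) + eps;
    double fpr = 24.0 * eps * (2.0 * s12 - s6) / r2; // (-dU/dr)/r along d
    for (int c = 0; c < 3; ++c) {
      F(j, c) += fpr * d[c];
      F(i, c) -= fpr * d[c];
    }
  }

  return List::create(_["energy"] = E, _["forces"] = F);
}

// collective variables ------------------------------------------------------

// [[Rcpp::export]]
List cpp_dihedral_cv(NumericMatrix coords, IntegerVector idx) {
  double phi, dphi[4][3];
  dihedral_geom(coords, idx[0] - 1, idx[1] - 1, idx[2] - 1, idx[3] - 1, phi, dphi);
  NumericMatrix G(4, 3);
  for (int t = 0; t < 4; ++t)
    for (int c = 0; c < 3; ++c)
      G(t, c) = dphi[t][c];
  return List::create(_["value"] = wrap_pi(phi), _["grad"] = G);
}

// coordination number between two atom groups with the rational switching
// function s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m); s(r0) = n/m exactly.
// [[Rcpp::export]]
List cpp_coordination_cv(NumericMatrix coords, IntegerVector g1, IntegerVector g2,
                         double r0, double nexp, double mexp) {
  int N = coords.nrow();
  NumericMatrix G(N, 3);
  double val = 0.0;
  for (int a = 0; a < g1.size(); ++a) {
    int i = g1[a] - 1;
    for (int b = 0; b < g2.size(); ++b) {
      int j = g2[b] - 1;
      double d[3], r2 = 0.0;
      for (int c = 0; c < 3; ++c) { d[c] = coords(j, c) - coords(i, c); r2 += d[c] * d[c]; }
      double r = std::sqrt(r2);
      double x = r / r0;
      double s, dsdr;
      if (std::fabs(x - 1.0) < 1e-7) {
        s = nexp / mexp;
        dsdr = nexp * (nexp - mexp) / (2.0 * mexp * r0);
      } else {
        double xn = std::pow(x, nexp), xm = std::pow(x, mexp);
        double den = 1.0 - xm;
        s = (1.0 - xn) / den;
        dsdr = (-nexp * std::pow(x, nexp - 1.0) * den
                + mexp * std::pow(x, mexp - 1.0) * (1.0 - xn)) / (r0 * den * den);
      }
      val += s;
      for (int c = 0; c < 3; ++c) {
        double g = dsdr * d[c] / r;
        G(j, c) += g;
        G(i, c) -= g;
      }
    }
  }
  return List::create(_["value"] = val, _["grad"] = G);
}

// parallel-bias potential ---------------------------------------------------

static inline double vg_one(double s, const NumericMatrix& h, bool periodic,
                            double* dv) {
  double v = 0.0, d = 0.0;
  for (int t = 0; t < h.nrow(); ++t) {
    double dx = s - h(t, 0);
    if (periodic) dx = wrap_pi(dx);
    double w = h(t, 1);
    double e = h(t, 2) * std::exp(-0.5 * dx * dx / (w * w));
    v += e;
    d += -e * dx / (w * w);
  }
  if (dv) *dv = d;
  return v;
}

// V_PB = -kBT log sum_j exp(-V_Gj(s_j)/kBT); hills: list of (n x 3) matrices
// (center, width, height) per CV. Returns V_PB, per-CV V_G and dV_PB/ds.
// [[Rcpp::export]]
List cpp_bias_eval(NumericVector cv, List hills, LogicalVector periodic, double kBT) {
  int M = cv.size();
  NumericVector vg(M), dvds(M), dvg(M);
  for (int j = 0; j < M; ++j) {
    NumericMatrix h = hills[j];
    double d;
    vg[j] = vg_one(cv[j], h, periodic[j], &d);
    dvg[j] = d;
  }
  // log-sum-exp with shift
  double mx = -vg[0] / kBT;
  for (int j = 1; j < M; ++j) mx = std::max(mx, -vg[j] / kBT);
  double Z = 0.0;
  for (int j = 0; j < M; ++j) Z += std::exp(-vg[j] / kBT - mx);
  double vpb = -kBT * (std::log(Z) + mx);
  for (int j = 0; j < M; ++j) {
    double pj = std::exp(-vg[j] / kBT - mx) / Z;
    dvds[j] = pj * dvg[j];
  }
  return List::create(_["vpb"] = vpb, _["vg"] = vg, _["dvds"] = dvds);
}

// V_PB for many frames (rows of cvmat), used for final unbiasing weights.
// [[Rcpp::export]]
NumericVector cpp_bias_many(NumericMatrix cvmat, List hills, LogicalVector periodic,
                            double kBT) {
  int F = cvmat.nrow(), M = cvmat.ncol();
  NumericVector out(F);
  for (int f = 0; f < F; ++f) {
    double mx = -1e300;
    std::vector<double> vg(M);
    for (int j = 0; j < M; ++j) {
      NumericMatrix h = hills[j];
      vg[j] = vg_one(cvmat(f, j), h, periodic[j], nullptr);
      mx = std::max(mx, -vg[j] / kBT);
    }
    double Z = 0.0;
    for (int j = 0; j < M; ++j) Z += std::exp(-vg[j] / kBT - mx);
    out[f] = -kBT * (std::log(Z) + mx);
  }
  return out;
}

// Fused per-step kernel: evaluate all CVs, the parallel-bias potential over
// the biased subset, and the bias force, in one call.
// cvdefs: list per CV of List(kind, atoms, g1, g2, r0, n, m); kind 1 =
// dihedral, 2 = coordination.  biased: 1-based indices of biased CVs into
// cvdefs; hills: one (n x 3) matrix per biased CV.
// [[Rcpp::export]]
List cpp_cv_bias_force(NumericMatrix coords, List cvdefs, IntegerVector biased,
                       List hills, LogicalVector periodic, double kBT) {
  int M = cvdefs.size(), N = coords.nrow();
  NumericVector vals(M);
  NumericMatrix F(N, 3);
  std::vector<std::vector<double>> grads(M);
  std::vector<std::vector<int>> gidx(M);
  for (int j = 0; j < M; ++j) {
    List def = cvdefs[j];
    int kind = as<int>(def["kind"]);
    if (kind == 1) {
      IntegerVector at = def["atoms"];
      double phi, dphi[4][3];
      dihedral_geom(coords, at[0] - 1, at[1] - 1, at[2] - 1, at[3] - 1,
                    phi, dphi);
      vals[j] = wrap_pi(phi);
      grads[j].resize(12);
      gidx[j].resize(4);
      for (int t = 0; t < 4; ++t) {
        gidx[j][t] = at[t] - 1;
        for (int c = 0; c < 3; ++c) grads[j][3 * t + c] = dphi[t][c];
      }
    } else {
      IntegerVector g1 = def["g1"], g2 = def["g2"];
      double r0 = as<double>(def["r0"]);
      double ne = as<double>(def["n"]), me = as<double>(def["m"]);
      List r = cpp_coordination_cv(coords, g1, g2, r0, ne, me);
      vals[j] = as<double>(r["value"]);
      NumericMatrix G = r["grad"];
      grads[j].resize(3 * N);
      gidx[j].resize(N);
      for (int i = 0; i < N; ++i) {
        gidx[j][i] = i;
        for (int c = 0; c < 3; ++c) grads[j][3 * i + c] = G(i, c);
      }
    }
  }
  int B = biased.size();
  double vpb = 0.0;
  if (B > 0) {
    std::vector<double> vg(B), dvg(B);
    double mx = -1e300;
    for (int b = 0; b < B; ++b) {
      NumericMatrix h = hills[b];
      double d;
      vg[b] = vg_one(vals[biased[b] - 1], h, periodic[b], &d);
      dvg[b] = d;
      mx = std::max(mx, -vg[b] / kBT);
    }
    double Z = 0.0;
    for (int b = 0; b < B; ++b) Z += std::exp(-vg[b] / kBT - mx);
    vpb = -kBT * (std::log(Z) + mx);
    for (int b = 0; b < B; ++b) {
      double dvds = std::exp(-vg[b] / kBT - mx) / Z * dvg[b];
      int j = biased[b] - 1;
      for (size_t t = 0; t < gidx[j].size(); ++t) {
        int a = gidx[j][t];
        F(a, 0) -= dvds * grads[j][3 * t + 0];
        F(a, 1) -= dvds * grads[j][3 * t + 1];
        F(a, 2) -= dvds * grads[j][3 * t + 2];
      }
    }
  }
  return List::create(_["vals"] = vals, _["vpb"] = vpb, _["force"] = F);
}

// V_G of one CV evaluated on a grid (free-energy profiles).
// [[Rcpp::export]]
NumericVector cpp_vg_grid(NumericVector grid, NumericMatrix hills, bool periodic) {
  NumericVector out(grid.size());
  for (int g = 0; g < grid.size(); ++g)
    out[g] = vg_one(grid[g], hills, periodic, nullptr);
  return out;
}
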