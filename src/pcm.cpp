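// C-PCM solute-surface electrostatics: interaction integrals between NDDO
// one-center charge distributions and a unit charge on a tessera (local-frame
// monopole/dipole/quadrupole potentials rotated onto the molecular frame by
// the direction cosines of the atom->tessera vector), their analytic
// derivatives, the nuclear surface potential, and assembly of the analytic
// part of the PCM energy gradient.
// The Klopman-Ohno additive rho terms are zero here by construction; the
// resulting bare point-multipole sums are kept finite by flooring every
// effective distance at 0.1 bohr.
// [[Rcpp::depends(RcppArmadillo)]]
#include "common.h"
using namespace arma;

static const int PIDX2[10][2] = {{0,0},{0,1},{0,2},{0,3},{1,1},{1,2},{1,3},{2,2},{2,3},{3,3}};

static const double RCLAMP = 0.1; // bohr

static inline double cinv(double x) { return 1.0 / std::max(x, RCLAMP); }
static inline double dcinv(double x) {
  return (x > RCLAMP) ? -1.0 / (x * x) : 0.0;
}

// local-frame potentials (au): ss, s-psigma, psigma-psigma, ppi-ppi
static void local_tess(const ElemPar& p, double R, double v[4], double dv[4]) {
  v[0] = cinv(R);
  dv[0] = dcinv(R);
  if (p.norb == 1) {
    v[1] = v[2] = v[3] = dv[1] = dv[2] = dv[3] = 0.0;
    return;
  }
  double dd = p.dd, qq = p.qq;
  v[1] = 0.5 * (cinv(R - dd) - cinv(R + dd));
  dv[1] = 0.5 * (dcinv(R - dd) - dcinv(R + dd));
  v[2] = 0.5 * cinv(R) + 0.25 * cinv(R - 2 * qq) + 0.25 * cinv(R + 2 * qq);
  dv[2] = 0.5 * dcinv(R) + 0.25 * dcinv(R - 2 * qq) + 0.25 * dcinv(R + 2 * qq);
  double s2 = R * R + 4 * qq * qq;
  double sq = std::sqrt(std::max(s2, RCLAMP * RCLAMP));
  v[3] = 0.5 * cinv(R) + 0.5 / sq;
  dv[3] = 0.5 * dcinv(R) - 0.5 * R / (sq * sq * sq);
  // (the ss monopole part of the p-p distributions is carried explicitly:
  //  v[2], v[3] include the 1/R monopole plus the quadrupole correction)
}

// packed 10-entry molecular-frame block; optionally its derivative w.r.t. the
// atom->tessera vector r (dT: 10 x 3)
static void tess_block(const ElemPar& p, const vec3& r, double* T, double* dT) {
  double R = norm(r);
  vec3 e = r / R;
  double v[4], dv[4];
  local_tess(p, R, v, dv);
  T[0] = v[0];
  if (p.norb == 4) {
    for (int a = 0; a < 3; ++a) T[1 + a] = e(a) * v[1];
    int pos = 4;
    for (int a = 0; a < 3; ++a)
      for (int b = a; b < 3; ++b) {
        double del = (a == b) ? 1.0 : 0.0;
        T[pos++] = e(a) * e(b) * v[2] + (del - e(a) * e(b)) * v[3];
      }
  } else {
    for (int t = 1; t < 10; ++t) T[t] = 0.0;
  }
  if (!dT) return;
  for (int t = 0; t < 30; ++t) dT[t] = 0.0;
  for (int c = 0; c < 3; ++c) dT[0 * 3 + c] = dv[0] * e(c);
  if (p.norb == 4) {
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) {
        double dea = ((a == c ? 1.0 : 0.0) - e(a) * e(c)) / R;
        dT[(1 + a) * 3 + c] = dv[1] * e(a) * e(c) + v[1] * dea;
      }
    int pos = 4;
    for (int a = 0; a < 3; ++a)
      for (int b = a; b < 3; ++b) {
        double del = (a == b) ? 1.0 : 0.0;
        for (int c = 0; c < 3; ++c) {
          double dea = ((a == c ? 1.0 : 0.0) - e(a) * e(c)) / R;
          double deb = ((b == c ? 1.0 : 0.0) - e(b) * e(c)) / R;
          double dprod = dea * e(b) + e(a) * deb;
          dT[pos * 3 + c] = (dv[2] - dv[3]) * e(a) * e(b) * e(c) +
                            dv[3] * del * e(c) + (v[2] - v[3]) * dprod;
        }
        pos++;
      }
  }
}

arma::mat tessera_integral_matrix(const mat& coords,
                                  const std::vector<ElemPar>& pars,
                                  const ivec& ielem, const mat& tpos,
                                  std::vector<int>& col_atom,
                                  std::vector<int>& col_pair) {
  int nat = ielem.n_elem;
  int nt = tpos.n_cols;
  col_atom.clear();
  col_pair.clear();
  for (int a = 0; a < nat; ++a) {
    int npair = (pars[ielem(a) - 1].norb == 4) ? 10 : 1;
    for (int t = 0; t < npair; ++t) {
      col_atom.push_back(a);
      col_pair.push_back(t);
    }
  }
  int n1c = col_atom.size();
  mat T(nt, n1c);
  double blk[10];
  for (int i = 0; i < nt; ++i) {
    int c = 0;
    for (int a = 0; a < nat; ++a) {
      const ElemPar& p = pars[ielem(a) - 1];
      vec3 r = tpos.col(i) - coords.col(a);
      tess_block(p, r, blk, nullptr);
      int npair = (p.norb == 4) ? 10 : 1;
      for (int t = 0; t < npair; ++t) T(i, c++) = blk[t];
    }
  }
  return T;
}

arma::vec nuclear_potential_vec(const mat& coords,
                                const std::vector<ElemPar>& pars,
                                const ivec& ielem, const mat& tpos) {
  int nat = ielem.n_elem;
  int nt = tpos.n_cols;
  vec V(nt, fill::zeros);
  for (int i = 0; i < nt; ++i)
    for (int a = 0; a < nat; ++a) {
      double r = norm(tpos.col(i) - coords.col(a));
      V(i) += pars[ielem(a) - 1].zcore * cinv(r);
    }
  return V;
}

// [[Rcpp::export]]
Rcpp::List cpp_tessera_integrals(const arma::mat& coords, const Rcpp::List& plist,
                                 const arma::ivec& ielem, const arma::mat& tpos) {
  std::vector<ElemPar> pars = unpack_params(plist);
  std::vector<int> ca, cp;
  mat T = tessera_integral_matrix(coords, pars, ielem, tpos, ca, cp);
  return Rcpp::List::create(
      Rcpp::Named("T") = T,
      Rcpp::Named("col_atom") = Rcpp::IntegerVector(ca.begin(), ca.end()),
      Rcpp::Named("col_pair") = Rcpp::IntegerVector(cp.begin(), cp.end()));
}

// single atom-tessera block with derivative, for the module surface and tests
// [[Rcpp::export]]
Rcpp::List cpp_tessera_block(const Rcpp::List& par, const arma::vec& rvec) {
  Rcpp::List pl = Rcpp::List::create(par);
  std::vector<ElemPar> pars = unpack_params(pl);
  double T[10], dT[30];
  tess_block(pars[0], vec3(rvec), T, dT);
  mat dTm(10, 3);
  for (int t = 0; t < 10; ++t)
    for (int c = 0; c < 3; ++c) dTm(t, c) = dT[t * 3 + c];
  return Rcpp::List::create(Rcpp::Named("T") = vec(T, 10),
                            Rcpp::Named("dT") = dTm);
}

// [[Rcpp::export]]
arma::vec cpp_nuclear_potential(const arma::mat& coords, const Rcpp::List& plist,
                                const arma::ivec& ielem, const arma::mat& tpos) {
  std::vector<ElemPar> pars = unpack_params(plist);
  return nuclear_potential_vec(coords, pars, ielem, tpos);
}

// d V_i^nuc / d x_A for one atom A: direct field term plus the rigid riding of
// the tesserae bound to sphere A. Returns nt x 3.
// [[Rcpp::export]]
arma::mat cpp_nuclear_potential_derivative(const arma::mat& coords,
                                           const Rcpp::List& plist,
                                           const arma::ivec& ielem,
                                           const arma::mat& tpos,
                                           const arma::ivec& tsphere,
                                           int atom_index) {
  std::vector<ElemPar> pars = unpack_params(plist);
  int nat = ielem.n_elem;
  int nt = tpos.n_cols;
  int A = atom_index - 1;
  mat out(nt, 3, fill::zeros);
  for (int i = 0; i < nt; ++i) {
    vec3 g(fill::zeros);
    // direct: d/dR_A of Z_A/|s_i - R_A|
    vec3 rA = tpos.col(i) - coords.col(A);
    double dA = norm(rA);
    if (dA > RCLAMP) g += pars[ielem(A) - 1].zcore * rA / (dA * dA * dA);
    if (tsphere(i) - 1 == A) {
      // riding: d/ds_i of the full nuclear potential, with ds_i = dR_A
      for (int b = 0; b < nat; ++b) {
        vec3 rb = tpos.col(i) - coords.col(b);
        double db = norm(rb);
        if (db > RCLAMP) g -= pars[ielem(b) - 1].zcore * rb / (db * db * db);
      }
    }
    out.row(i) = g.t();
  }
  return out;
}

// d V_i^el / d x_A at fixed density (analytic chain rule through the rotated
// tessera integrals), including riding terms. Returns nt x 3.
// [[Rcpp::export]]
arma::mat cpp_electronic_potential_derivative(const arma::mat& coords,
                                              const Rcpp::List& plist,
                                              const arma::ivec& ielem,
                                              const arma::mat& P,
                                              const arma::mat& tpos,
                                              const arma::ivec& tsphere,
                                              int atom_index) {
  std::vector<ElemPar> pars = unpack_params(plist);
  int nat = ielem.n_elem;
  int nt = tpos.n_cols;
  int A = atom_index - 1;
  std::vector<int> off(nat), nor(nat);
  int nbf = 0;
  for (int a = 0; a < nat; ++a) {
    off[a] = nbf;
    nor[a] = pars[ielem(a) - 1].norb;
    nbf += nor[a];
  }
  mat out(nt, 3, fill::zeros);
  double T[10], dT[30];
  for (int i = 0; i < nt; ++i) {
    vec3 g(fill::zeros);
    bool rides = (tsphere(i) - 1 == A);
    for (int b = 0; b < nat; ++b) {
      if (b != A && !rides) continue;
      const ElemPar& p = pars[ielem(b) - 1];
      vec3 r = tpos.col(i) - coords.col(b);
      tess_block(p, r, T, dT);
      int npair = (p.norb == 4) ? 10 : 1;
      vec3 gpair(fill::zeros); // sum_t Pfac_t dT_t/dr
      for (int t = 0; t < npair; ++t) {
        int ii = off[b] + PIDX2[t][0], jj = off[b] + PIDX2[t][1];
        double pf = (ii == jj) ? P(ii, jj) : 2.0 * P(ii, jj);
        for (int c = 0; c < 3; ++c) gpair(c) += pf * dT[t * 3 + c];
      }
      // V_el contribution from atom b: -sum Pfac T(r), r = s_i - R_b
      if (b == A) g += gpair;        // d/dR_A = +sum Pfac dT/dr
      if (rides) g -= gpair;         // d/ds_i = -sum Pfac dT/dr
    }
    out.row(i) = g.t();
  }
  return out;
}

// Analytic part of the PCM free-energy gradient (hartree/bohr):
//   q^T dV/dx (nuclear + electronic at fixed density, with tesserae riding
//   rigidly on their parent spheres) plus the inter-sphere part of
//   (1/2f) q^T dD/dx q.  The intra-sphere D entries and the tessera-area
//   diagonal are geometry-rigid / handled numerically elsewhere.
// [[Rcpp::export]]
arma::vec cpp_pcm_gradient_analytic(const arma::mat& coords,
                                    const Rcpp::List& plist,
                                    const arma::ivec& ielem,
                                    const arma::mat& P, const arma::mat& tpos,
                                    const arma::ivec& tsphere,
                                    const arma::vec& q, double f,
                                    const arma::vec& area, double kdiag) {
  std::vector<ElemPar> pars = unpack_params(plist);
  int nat = ielem.n_elem;
  int nt = tpos.n_cols;
  std::vector<int> off(nat), nor(nat);
  int nbf = 0;
  for (int a = 0; a < nat; ++a) {
    off[a] = nbf;
    nor[a] = pars[ielem(a) - 1].norb;
    nbf += nor[a];
  }
  vec g(3 * nat, fill::zeros);
  double T[10], dT[30];

  for (int i = 0; i < nt; ++i) {
    int Ai = tsphere(i) - 1;
    vec3 ride_sum(fill::zeros); // sum_b dV_i/dR_b ; dV_i/ds_i = -ride_sum
    for (int b = 0; b < nat; ++b) {
      const ElemPar& p = pars[ielem(b) - 1];
      vec3 r = tpos.col(i) - coords.col(b);
      double d = norm(r);
      vec3 gb(fill::zeros);
      if (d > RCLAMP) gb += p.zcore * r / (d * d * d); // nuclear
      tess_block(p, r, T, dT);
      int npair = (p.norb == 4) ? 10 : 1;
      for (int t = 0; t < npair; ++t) {
        int ii = off[b] + PIDX2[t][0], jj = off[b] + PIDX2[t][1];
        double pf = (ii == jj) ? P(ii, jj) : 2.0 * P(ii, jj);
        for (int c = 0; c < 3; ++c) gb(c) += pf * dT[t * 3 + c];
      }
      ride_sum += gb;
      for (int c = 0; c < 3; ++c) g(3 * b + c) += q(i) * gb(c);
    }
    for (int c = 0; c < 3; ++c) g(3 * Ai + c) -= q(i) * ride_sum(c);
  }

  // inter-sphere D derivative at fixed areas: (1/f) sum_{i on A, j not on A}
  // q_i q_j d D_ij/ds_i with the tessera-size damped coupling
  // D_ij = 1/sqrt(d^2 + w_i w_j)
  const double PI_ = 3.14159265358979323846;
  vec w = sqrt(area / PI_);
  for (int i = 0; i < nt; ++i) {
    int Ai = tsphere(i) - 1;
    for (int j = 0; j < nt; ++j) {
      if (j == i || tsphere(j) - 1 == Ai) continue;
      vec3 rij = tpos.col(i) - tpos.col(j);
      double d2 = dot(rij, rij) + w(i) * w(j);
      vec3 gd = -rij / (d2 * std::sqrt(d2));
      for (int c = 0; c < 3; ++c) g(3 * Ai + c) += (1.0 / f) * q(i) * q(j) * gd(c);
    }
  }
  return g;
}
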