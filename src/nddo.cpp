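// NDDO semi-empirical core: exact Slater overlaps (A/B auxiliary integrals),
// two-center two-electron integrals in the point-multipole representation with
// Klopman-Ohno damping, core Hamiltonian, core-core repulsion (MNDO screening
// plus AM1/PM3 Gaussian corrections), and a restricted closed-shell SCF with
// DIIS and an optional C-PCM coupling rebuilt from the density each iteration.
// [[Rcpp::depends(RcppArmadillo)]]
#include "common.h"
#include <deque>
using namespace arma;

std::vector<ElemPar> unpack_params(const Rcpp::List& plist) {
  std::vector<ElemPar> out;
  for (R_xlen_t i = 0; i < plist.size(); ++i) {
    Rcpp::List e = plist[i];
    ElemPar p;
    p.z = Rcpp::as<int>(e["z"]);
    p.zcore = Rcpp::as<double>(e["zcore"]);
    p.norb = Rcpp::as<int>(e["norb"]);
    p.npq = Rcpp::as<int>(e["npq"]);
    p.uss = Rcpp::as<double>(e["uss"]);
    p.upp = Rcpp::as<double>(e["upp"]);
    p.zs = Rcpp::as<double>(e["zs"]);
    p.zp = Rcpp::as<double>(e["zp"]);
    p.betas = Rcpp::as<double>(e["betas"]);
    p.betap = Rcpp::as<double>(e["betap"]);
    p.alpha = Rcpp::as<double>(e["alpha"]);
    p.gss = Rcpp::as<double>(e["gss"]);
    p.gsp = Rcpp::as<double>(e["gsp"]);
    p.gpp = Rcpp::as<double>(e["gpp"]);
    p.gp2 = Rcpp::as<double>(e["gp2"]);
    p.hsp = Rcpp::as<double>(e["hsp"]);
    p.gauss = Rcpp::as<arma::mat>(e["gauss"]);
    p.dd = Rcpp::as<double>(e["dd"]);
    p.qq = Rcpp::as<double>(e["qq"]);
    p.rho0 = Rcpp::as<double>(e["rho0"]);
    p.rho1 = Rcpp::as<double>(e["rho1"]);
    p.rho2 = Rcpp::as<double>(e["rho2"]);
    p.eisol = Rcpp::as<double>(e["eisol"]);
    p.eheat = Rcpp::as<double>(e["eheat"]);
    out.push_back(p);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Slater-orbital overlaps via the classical auxiliary integrals
//   A_k(p) = int_1^inf  x^k exp(-p x) dx
//   B_k(t) = int_-1^1   y^k exp(-t y) dy
// in prolate spheroidal coordinates.  Exact for 1s/2s/2p pairs.
// ---------------------------------------------------------------------------
static void a_aux(double p, int kmax, double* A) {
  double ep = std::exp(-p);
  A[0] = ep / p;
  for (int k = 1; k <= kmax; ++k) A[k] = (ep + k * A[k - 1]) / p;
}

static void b_aux(double t, int kmax, double* B) {
  if (std::fabs(t) < 1.0) {      // series, stable near t = 0
    for (int k = 0; k <= kmax; ++k) {
      double s = 0.0, term = 1.0; // (-t)^m / m!
      for (int m = 0; m <= 40; ++m) {
        if ((k + m) % 2 == 0) s += term * 2.0 / (k + m + 1);
        term *= -t / (m + 1.0);
        if (std::fabs(term) < 1e-17) break;
      }
      B[k] = s;
    }
  } else {
    double eq = std::exp(t), emq = std::exp(-t);
    B[0] = (eq - emq) / t;
    for (int k = 1; k <= kmax; ++k) {
      double sgn = (k % 2 == 0) ? 1.0 : -1.0;
      B[k] = (sgn * eq - emq) / t + (k / t) * B[k - 1];
    }
  }
}

// tiny bivariate polynomial in (xi, eta); degree capped well above need
struct Poly {
  double c[9][9];
  Poly() { std::memset(c, 0, sizeof(c)); }
};

static Poly pmul(const Poly& a, const Poly& b) {
  Poly r;
  for (int i = 0; i < 9; ++i)
    for (int j = 0; j < 9; ++j) {
      if (a.c[i][j] == 0.0) continue;
      for (int k = 0; k + i < 9; ++k)
        for (int l = 0; l + j < 9; ++l) {
          if (b.c[k][l] == 0.0) continue;
          r.c[i + k][j + l] += a.c[i][j] * b.c[k][l];
        }
    }
  return r;
}

// overlap of two Slater orbitals in the local frame (z axis from A to B).
// l: 0 = s, 1 = p.  m: 0 = sigma, 1 = pi (requires l1 = l2 = 1).
// R in bohr; exact analytic value.
double sto_overlap_local(int n1, int l1, double zeta1,
                         int n2, int l2, double zeta2,
                         double R, int m) {
  const double PI = 3.14159265358979323846;
  Poly P;
  P.c[0][0] = 1.0;
  int rpow = 3; // from the volume element (R/2)^3 (xi^2 - eta^2)

  Poly f;
  if (l1 == 0 && n1 == 2) {            // r_A = (R/2)(xi + eta)
    f = Poly(); f.c[1][0] = 1.0; f.c[0][1] = 1.0; P = pmul(P, f); rpow++;
  } else if (l1 == 1 && m == 0) {      // z_A = (R/2)(1 + xi eta)
    f = Poly(); f.c[0][0] = 1.0; f.c[1][1] = 1.0; P = pmul(P, f); rpow++;
  }
  if (l2 == 0 && n2 == 2) {            // r_B = (R/2)(xi - eta)
    f = Poly(); f.c[1][0] = 1.0; f.c[0][1] = -1.0; P = pmul(P, f); rpow++;
  } else if (l2 == 1 && m == 0) {      // z_B = (R/2)(xi eta - 1)
    f = Poly(); f.c[0][0] = -1.0; f.c[1][1] = 1.0; P = pmul(P, f); rpow++;
  }
  if (m == 1) {                        // x_A x_B -> (R/2)^2 (xi^2-1)(1-eta^2) cos^2
    f = Poly();
    f.c[2][0] = 1.0; f.c[0][0] = -1.0; f.c[2][2] = -1.0; f.c[0][2] = 1.0;
    P = pmul(P, f); rpow += 2;
  }
  f = Poly(); f.c[2][0] = 1.0; f.c[0][2] = -1.0; // volume factor
  P = pmul(P, f);

  double p = 0.5 * R * (zeta1 + zeta2);
  double t = 0.5 * R * (zeta1 - zeta2);
  double A[9], B[9];
  a_aux(p, 8, A);
  b_aux(t, 8, B);
  double s = 0.0;
  for (int i = 0; i < 9; ++i)
    for (int j = 0; j < 9; ++j)
      if (P.c[i][j] != 0.0) s += P.c[i][j] * A[i] * B[j];

  auto radnorm = [](int n, double zt) {
    double fact2n = (n == 1) ? 2.0 : 24.0;
    return std::pow(2.0 * zt, n + 0.5) / std::sqrt(fact2n);
  };
  double ang1 = (l1 == 0) ? 1.0 / std::sqrt(4.0 * PI) : std::sqrt(3.0 / (4.0 * PI));
  double ang2 = (l2 == 0) ? 1.0 / std::sqrt(4.0 * PI) : std::sqrt(3.0 / (4.0 * PI));
  double phifac = (m == 0) ? 2.0 * PI : PI;
  return radnorm(n1, zeta1) * radnorm(n2, zeta2) * ang1 * ang2 * phifac *
         std::pow(0.5 * R, rpow) * s;
}

// local (z = A->B) to molecular frame rotation for an (s, px, py, pz) basis
static mat::fixed<4, 4> frame_rotation(const vec3& u) {
  vec3 zl = u;
  vec3 ref = (std::fabs(u(2)) < 0.9) ? vec3({0., 0., 1.}) : vec3({1., 0., 0.});
  vec3 xl = normalise(cross(ref, zl));
  vec3 yl = cross(zl, xl);
  mat::fixed<4, 4> O;
  O.zeros();
  O(0, 0) = 1.0;
  for (int i = 0; i < 3; ++i) {
    O(i + 1, 1) = xl(i);
    O(i + 1, 2) = yl(i);
    O(i + 1, 3) = zl(i);
  }
  return O;
}

arma::mat overlap_block(const ElemPar& pa, const ElemPar& pb, const vec3& rab) {
  double R = norm(rab);
  mat S(4, 4, fill::zeros);
  S(0, 0) = sto_overlap_local(pa.npq, 0, pa.zs, pb.npq, 0, pb.zs, R, 0);
  if (pb.norb == 4)
    S(0, 3) = sto_overlap_local(pa.npq, 0, pa.zs, pb.npq, 1, pb.zp, R, 0);
  if (pa.norb == 4)
    S(3, 0) = sto_overlap_local(pa.npq, 1, pa.zp, pb.npq, 0, pb.zs, R, 0);
  if (pa.norb == 4 && pb.norb == 4) {
    S(3, 3) = sto_overlap_local(pa.npq, 1, pa.zp, pb.npq, 1, pb.zp, R, 0);
    double spi = sto_overlap_local(pa.npq, 1, pa.zp, pb.npq, 1, pb.zp, R, 1);
    S(1, 1) = spi;
    S(2, 2) = spi;
  }
  mat::fixed<4, 4> O = frame_rotation(rab / R);
  return O * S * O.t();
}

// ---------------------------------------------------------------------------
// Two-center two-electron integrals: each one-center orbital-pair charge
// distribution is a point-multipole configuration (monopole, dipole with
// charge separation D1, linear/square quadrupole with separation D2);
// configuration-configuration terms are damped Coulomb sums
//   sum q_i q_j / sqrt(r_ij^2 + (rho_l(A) + rho_l'(B))^2).
// ---------------------------------------------------------------------------
struct Cfg {
  int l = 0;           // multipole order (selects rho)
  int n = 0;           // number of point charges
  double q[4];
  double x[4], y[4], z[4];
};

static void add_charge(Cfg& c, double q, double x, double y, double z) {
  c.q[c.n] = q; c.x[c.n] = x; c.y[c.n] = y; c.z[c.n] = z; c.n++;
}

// pair types in packed order:
// 0 ss, 1 s-px, 2 s-py, 3 s-pz, 4 xx, 5 xy, 6 xz, 7 yy, 8 yz, 9 zz
static int pair_cfgs(int type, double dd, double qq, Cfg* out) {
  Cfg mono; mono.l = 0; add_charge(mono, 1.0, 0, 0, 0);
  auto dip = [&](double ux, double uy, double uz) {
    Cfg c; c.l = 1;
    add_charge(c, 0.5, dd * ux, dd * uy, dd * uz);
    add_charge(c, -0.5, -dd * ux, -dd * uy, -dd * uz);
    return c;
  };
  auto qlin = [&](double ux, double uy, double uz) {
    Cfg c; c.l = 2;
    add_charge(c, 0.25, 2 * qq * ux, 2 * qq * uy, 2 * qq * uz);
    add_charge(c, 0.25, -2 * qq * ux, -2 * qq * uy, -2 * qq * uz);
    add_charge(c, -0.5, 0, 0, 0);
    return c;
  };
  // square quadrupole in the plane of axes a and b
  auto qsq = [&](int a, int b) {
    Cfg c; c.l = 2;
    double pos[3];
    auto setp = [&](double sa, double sb, double q) {
      pos[0] = pos[1] = pos[2] = 0.0;
      pos[a] = sa * qq; pos[b] = sb * qq;
      add_charge(c, q, pos[0], pos[1], pos[2]);
    };
    setp(1, 1, 0.25); setp(-1, -1, 0.25); setp(1, -1, -0.25); setp(-1, 1, -0.25);
    return c;
  };
  switch (type) {
    case 0: out[0] = mono; return 1;
    case 1: out[0] = dip(1, 0, 0); return 1;
    case 2: out[0] = dip(0, 1, 0); return 1;
    case 3: out[0] = dip(0, 0, 1); return 1;
    case 4: out[0] = mono; out[1] = qlin(1, 0, 0); return 2;
    case 5: out[0] = qsq(0, 1); return 1;
    case 6: out[0] = qsq(0, 2); return 1;
    case 7: out[0] = mono; out[1] = qlin(0, 1, 0); return 2;
    case 8: out[0] = qsq(1, 2); return 1;
    case 9: out[0] = mono; out[1] = qlin(0, 0, 1); return 2;
  }
  return 0;
}

static double rho_of(const ElemPar& p, int l) {
  return (l == 0) ? p.rho0 : (l == 1 ? p.rho1 : p.rho2);
}

static double cfg_interact(const Cfg& a, const Cfg& b, double R,
                           double rho_a, double rho_b) {
  double add2 = (rho_a + rho_b) * (rho_a + rho_b);
  double s = 0.0;
  for (int i = 0; i < a.n; ++i)
    for (int j = 0; j < b.n; ++j) {
      double dx = b.x[j] - a.x[i];
      double dy = b.y[j] - a.y[i];
      double dz = b.z[j] + R - a.z[i];
      s += a.q[i] * b.q[j] / std::sqrt(dx * dx + dy * dy + dz * dz + add2);
    }
  return s;
}

static const int PIDX[10][2] = {{0,0},{0,1},{0,2},{0,3},{1,1},{1,2},{1,3},{2,2},{2,3},{3,3}};

// local-frame 10x10 two-electron block (atomic units)
static void local_w(const ElemPar& pa, const ElemPar& pb, double R,
                    double wloc[10][10]) {
  Cfg ca[2], cb[2];
  int nta = (pa.norb == 4) ? 10 : 1;
  int ntb = (pb.norb == 4) ? 10 : 1;
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 10; ++j) wloc[i][j] = 0.0;
  for (int ti = 0; ti < nta; ++ti) {
    int na = pair_cfgs(ti, pa.dd, pa.qq, ca);
    for (int tj = 0; tj < ntb; ++tj) {
      int nb = pair_cfgs(tj, pb.dd, pb.qq, cb);
      double v = 0.0;
      for (int i = 0; i < na; ++i)
        for (int j = 0; j < nb; ++j)
          v += cfg_interact(ca[i], cb[j], R, rho_of(pa, ca[i].l), rho_of(pb, cb[j].l));
      wloc[ti][tj] = v;
    }
  }
}

// rotate a full 4x4x4x4 tensor by orbital rotation O (first two indices on A,
// last two on B); contraction mode by mode
static void rotate4(const mat::fixed<4, 4>& O, double w[256]) {
  double t[256];
  // index ((i*4+j)*4+k)*4+l
  for (int pass = 0; pass < 4; ++pass) {
    for (int i = 0; i < 256; ++i) t[i] = 0.0;
    int stride;
    switch (pass) { case 0: stride = 64; break; case 1: stride = 16; break;
                    case 2: stride = 4; break; default: stride = 1; }
    for (int outer = 0; outer < 256 / (stride * 4); ++outer)
      for (int inner = 0; inner < stride; ++inner) {
        int base = outer * stride * 4 + inner;
        double v0 = w[base], v1 = w[base + stride],
               v2 = w[base + 2 * stride], v3 = w[base + 3 * stride];
        for (int a = 0; a < 4; ++a)
          t[base + a * stride] = O(a, 0) * v0 + O(a, 1) * v1 + O(a, 2) * v2 + O(a, 3) * v3;
      }
    std::memcpy(w, t, sizeof(t));
  }
}

// full molecular-frame two-electron tensor for a pair, in eV
void pair_w_tensor(const ElemPar& pa, const ElemPar& pb, const vec3& rab,
                   double w[256]) {
  double R = norm(rab);
  double wloc[10][10];
  local_w(pa, pb, R, wloc);
  // expand packed pairs to full local tensor
  for (int i = 0; i < 256; ++i) w[i] = 0.0;
  int nta = (pa.norb == 4) ? 10 : 1;
  int ntb = (pb.norb == 4) ? 10 : 1;
  for (int ti = 0; ti < nta; ++ti) {
    int i = PIDX[ti][0], j = PIDX[ti][1];
    for (int tj = 0; tj < ntb; ++tj) {
      int k = PIDX[tj][0], l = PIDX[tj][1];
      double v = wloc[ti][tj];
      int idx[4][2] = {{i, j}, {j, i}, {i, j}, {j, i}};
      (void)idx;
      w[((i * 4 + j) * 4 + k) * 4 + l] = v;
      w[((j * 4 + i) * 4 + k) * 4 + l] = v;
      w[((i * 4 + j) * 4 + l) * 4 + k] = v;
      w[((j * 4 + i) * 4 + l) * 4 + k] = v;
    }
  }
  mat::fixed<4, 4> O = frame_rotation(rab / R);
  rotate4(O, w);
  for (int i = 0; i < 256; ++i) w[i] *= EV_PER_HARTREE;
}

arma::mat pair_repulsion_block(const ElemPar& pa, const ElemPar& pb,
                               const vec3& rab) {
  double w[256];
  pair_w_tensor(pa, pb, rab, w);
  mat out(10, 10, fill::zeros);
  for (int ti = 0; ti < 10; ++ti)
    for (int tj = 0; tj < 10; ++tj) {
      int i = PIDX[ti][0], j = PIDX[ti][1], k = PIDX[tj][0], l = PIDX[tj][1];
      out(ti, tj) = w[((i * 4 + j) * 4 + k) * 4 + l];
    }
  return out;
}

// core-attraction contributions (eV): e1a over pairs on A from core B, and
// e1b over pairs on B from core A; returned as packed 10-vectors
void pair_core_attraction(const ElemPar& pa, const ElemPar& pb,
                          const vec3& rab, arma::vec& e1a, arma::vec& e1b) {
  double R = norm(rab);
  Cfg core; core.l = 0; add_charge(core, 1.0, 0, 0, 0);
  Cfg cc[2];
  mat::fixed<4, 4> O = frame_rotation(rab / R);

  auto one_side = [&](const ElemPar& pd, const ElemPar& pcore, bool dist_on_a,
                      arma::vec& out) {
    out.zeros(10);
    int nt = (pd.norb == 4) ? 10 : 1;
    mat M(4, 4, fill::zeros);
    for (int ti = 0; ti < nt; ++ti) {
      int nc = pair_cfgs(ti, pd.dd, pd.qq, cc);
      double v = 0.0;
      for (int i = 0; i < nc; ++i) {
        double r_d = rho_of(pd, cc[i].l);
        double r_c = pcore.rho0;
        v += dist_on_a ? cfg_interact(cc[i], core, R, r_d, r_c)
                       : cfg_interact(core, cc[i], R, r_c, r_d);
      }
      M(PIDX[ti][0], PIDX[ti][1]) = v;
      M(PIDX[ti][1], PIDX[ti][0]) = v;
    }
    M = O * M * O.t();
    for (int ti = 0; ti < 10; ++ti)
      out(ti) = -pcore.zcore * M(PIDX[ti][0], PIDX[ti][1]) * EV_PER_HARTREE;
  };
  one_side(pa, pb, true, e1a);
  one_side(pb, pa, false, e1b);
}

double core_core_pair(const ElemPar& pa, const ElemPar& pb, double r_bohr) {
  Cfg mono_a; mono_a.l = 0; add_charge(mono_a, 1.0, 0, 0, 0);
  double gss = cfg_interact(mono_a, mono_a, r_bohr, pa.rho0, pb.rho0) * EV_PER_HARTREE;
  double ra = r_bohr * ANGSTROM_PER_BOHR;
  bool nh_a = (pa.z == 7 || pa.z == 8) && pb.z == 1;
  bool nh_b = (pb.z == 7 || pb.z == 8) && pa.z == 1;
  double scale = 1.0 + std::exp(-pa.alpha * ra) * (nh_a ? ra : 1.0) +
                 std::exp(-pb.alpha * ra) * (nh_b ? ra : 1.0);
  double e = pa.zcore * pb.zcore * gss * scale;
  double t = pa.zcore * pb.zcore / ra;
  for (arma::uword k = 0; k < pa.gauss.n_rows; ++k)
    e += t * pa.gauss(k, 0) * std::exp(-pa.gauss(k, 1) * std::pow(ra - pa.gauss(k, 2), 2));
  for (arma::uword k = 0; k < pb.gauss.n_rows; ++k)
    e += t * pb.gauss(k, 0) * std::exp(-pb.gauss(k, 1) * std::pow(ra - pb.gauss(k, 2), 2));
  return e;
}

// ---------------------------------------------------------------------------
// integral assembly over a molecule
// ---------------------------------------------------------------------------
struct Ints {
  int nat = 0, nbf = 0;
  std::vector<int> off, nor;
  mat H;       // core Hamiltonian, eV
  double enuc = 0.0;
  std::vector<int> ia, ib;                  // pair atoms
  std::vector<std::vector<double>> w;       // per pair: full 256 tensor (eV)
};

static void basis_layout(const std::vector<ElemPar>& pars, const ivec& ielem,
                         std::vector<int>& off, std::vector<int>& nor, int& nbf) {
  int nat = ielem.n_elem;
  off.resize(nat); nor.resize(nat);
  nbf = 0;
  for (int a = 0; a < nat; ++a) {
    off[a] = nbf;
    nor[a] = pars[ielem(a) - 1].norb;
    nbf += nor[a];
  }
}

static Ints build_ints(const mat& coords, const std::vector<ElemPar>& pars,
                       const ivec& ielem) {
  Ints I;
  I.nat = ielem.n_elem;
  basis_layout(pars, ielem, I.off, I.nor, I.nbf);
  I.H.zeros(I.nbf, I.nbf);
  for (int a = 0; a < I.nat; ++a) {
    const ElemPar& p = pars[ielem(a) - 1];
    I.H(I.off[a], I.off[a]) = p.uss;
    for (int k = 1; k < I.nor[a]; ++k) I.H(I.off[a] + k, I.off[a] + k) = p.upp;
  }
  for (int a = 0; a < I.nat; ++a) {
    const ElemPar& pa = pars[ielem(a) - 1];
    for (int b = a + 1; b < I.nat; ++b) {
      const ElemPar& pb = pars[ielem(b) - 1];
      vec3 rab = coords.col(b) - coords.col(a);
      double R = norm(rab);
      if (R * ANGSTROM_PER_BOHR < 1e-3)
        Rcpp::stop("overlapping nuclei");
      I.ia.push_back(a); I.ib.push_back(b);
      std::vector<double> w(256);
      pair_w_tensor(pa, pb, rab, w.data());
      I.w.push_back(std::move(w));

      vec e1a, e1b;
      pair_core_attraction(pa, pb, rab, e1a, e1b);
      int nta = (pa.norb == 4) ? 10 : 1, ntb = (pb.norb == 4) ? 10 : 1;
      for (int t = 0; t < nta; ++t) {
        int i = I.off[a] + PIDX[t][0], j = I.off[a] + PIDX[t][1];
        I.H(i, j) += e1a(t);
        if (i != j) I.H(j, i) += e1a(t);
      }
      for (int t = 0; t < ntb; ++t) {
        int i = I.off[b] + PIDX[t][0], j = I.off[b] + PIDX[t][1];
        I.H(i, j) += e1b(t);
        if (i != j) I.H(j, i) += e1b(t);
      }
      mat S = overlap_block(pa, pb, rab);
      for (int i = 0; i < I.nor[a]; ++i)
        for (int k = 0; k < I.nor[b]; ++k) {
          double bi = (i == 0) ? pa.betas : pa.betap;
          double bk = (k == 0) ? pb.betas : pb.betap;
          double h = 0.5 * (bi + bk) * S(i, k);
          I.H(I.off[a] + i, I.off[b] + k) = h;
          I.H(I.off[b] + k, I.off[a] + i) = h;
        }
      I.enuc += core_core_pair(pa, pb, R);
    }
  }
  return I;
}

// closed-shell two-electron Fock contribution (eV)
static mat fock2e(const Ints& I, const std::vector<ElemPar>& pars,
                  const ivec& ielem, const mat& P) {
  mat F(I.nbf, I.nbf, fill::zeros);
  // one-center terms
  for (int a = 0; a < I.nat; ++a) {
    const ElemPar& p = pars[ielem(a) - 1];
    int o = I.off[a];
    if (I.nor[a] == 1) {
      F(o, o) += 0.5 * P(o, o) * p.gss;
      continue;
    }
    double psum = P(o + 1, o + 1) + P(o + 2, o + 2) + P(o + 3, o + 3);
    F(o, o) += 0.5 * P(o, o) * p.gss + psum * (p.gsp - 0.5 * p.hsp);
    for (int k = 1; k <= 3; ++k) {
      F(o + k, o + k) += P(o, o) * (p.gsp - 0.5 * p.hsp) +
                         0.5 * P(o + k, o + k) * p.gpp +
                         (psum - P(o + k, o + k)) * (1.25 * p.gp2 - 0.25 * p.gpp);
      F(o, o + k) += P(o, o + k) * (1.5 * p.hsp - 0.5 * p.gsp);
      F(o + k, o) = F(o, o + k);
      for (int l = k + 1; l <= 3; ++l) {
        F(o + k, o + l) += P(o + k, o + l) * (0.75 * p.gpp - 1.25 * p.gp2);
        F(o + l, o + k) = F(o + k, o + l);
      }
    }
  }
  // two-center terms
  for (size_t np = 0; np < I.ia.size(); ++np) {
    int a = I.ia[np], b = I.ib[np];
    int oa = I.off[a], ob = I.off[b];
    int na = I.nor[a], nb = I.nor[b];
    const double* w = I.w[np].data();
    for (int i = 0; i < na; ++i)
      for (int j = 0; j < na; ++j) {
        double s = 0.0;
        for (int k = 0; k < nb; ++k)
          for (int l = 0; l < nb; ++l)
            s += P(ob + k, ob + l) * w[((i * 4 + j) * 4 + k) * 4 + l];
        F(oa + i, oa + j) += s;
      }
    for (int k = 0; k < nb; ++k)
      for (int l = 0; l < nb; ++l) {
        double s = 0.0;
        for (int i = 0; i < na; ++i)
          for (int j = 0; j < na; ++j)
            s += P(oa + i, oa + j) * w[((i * 4 + j) * 4 + k) * 4 + l];
        F(ob + k, ob + l) += s;
      }
    for (int i = 0; i < na; ++i)
      for (int k = 0; k < nb; ++k) {
        double s = 0.0;
        for (int j = 0; j < na; ++j)
          for (int l = 0; l < nb; ++l)
            s += P(oa + j, ob + l) * w[((i * 4 + j) * 4 + k) * 4 + l];
        F(oa + i, ob + k) -= 0.5 * s;
        F(ob + k, oa + i) = F(oa + i, ob + k);
      }
  }
  return F;
}

// ---------------------------------------------------------------------------
// C-PCM coupling pieces used inside the SCF (tessera integrals computed in
// pcm.cpp; here we only need the assembled operator pieces passed from R or
// precomputed via callbacks declared in common.h)
// ---------------------------------------------------------------------------
arma::mat tessera_integral_matrix(const mat& coords,
                                  const std::vector<ElemPar>& pars,
                                  const ivec& ielem, const mat& tpos,
                                  std::vector<int>& col_atom,
                                  std::vector<int>& col_pair);
arma::vec nuclear_potential_vec(const mat& coords,
                                const std::vector<ElemPar>& pars,
                                const ivec& ielem, const mat& tpos);

struct PcmCtx {
  bool active = false;
  mat tpos;        // 3 x nt (bohr)
  vec area;        // nt
  ivec sphere;     // parent sphere per tessera
  double f = 0.0;
  double kdiag = 1.0694;
  std::string solver = "direct";
  double cg_tol = 1e-8;
  // precomputed
  mat T;                 // nt x n1c
  std::vector<int> col_atom, col_pair;
  vec vnuc;
  mat D;                 // explicit when direct
  mat Dchol;
  bool have_chol = false;
  vec q_prev;
};

// Representative points of cut tesserae on different spheres can nearly
// coincide along intersection seams; a bare 1/d there destroys the positive
// definiteness of the C-PCM matrix and makes the energy surface pathological.
// Inter-sphere couplings are therefore damped on the tessera size scale,
//   D_ij = 1 / sqrt(d^2 + w_i w_j),  w = sqrt(a/pi),
// which leaves well-separated pairs untouched, is smooth in both positions
// and areas, and is always below the geometric mean of the diagonals.
// Same-sphere pairs (rigid, never degenerate) keep the exact 1/d with a
// safety cap.
constexpr double DMAT_CAP = 0.95;

double dmat_offdiag(double d, bool same_sphere, double wi, double wj,
                    double kdi, double kdj) {
  if (same_sphere) return std::min(1.0 / d, DMAT_CAP * std::sqrt(kdi * kdj));
  return 1.0 / std::sqrt(d * d + wi * wj);
}

static mat build_dmat(const mat& tpos, const vec& area, const ivec& sphere,
                      double kdiag) {
  int nt = area.n_elem;
  mat D(nt, nt);
  const double FOURPI = 4.0 * 3.14159265358979323846;
  const double PI = 3.14159265358979323846;
  vec w = sqrt(area / PI);
  for (int i = 0; i < nt; ++i)
    D(i, i) = kdiag * std::sqrt(FOURPI / area(i));
  for (int i = 0; i < nt; ++i)
    for (int j = i + 1; j < nt; ++j) {
      double d = norm(tpos.col(i) - tpos.col(j));
      D(i, j) = D(j, i) = dmat_offdiag(d, sphere(i) == sphere(j), w(i), w(j),
                                       D(i, i), D(j, j));
    }
  return D;
}

// conjugate gradient for D q = rhs with D given implicitly
static vec cg_solve(const mat& tpos, const vec& area, const ivec& sphere,
                    double kdiag, const vec& rhs, const vec& q0, double tol,
                    int maxit, int& iters, bool& ok, const mat* Dexp) {
  int nt = rhs.n_elem;
  const double FOURPI = 4.0 * 3.14159265358979323846;
  const double PI = 3.14159265358979323846;
  vec kd(nt), w(nt);
  for (int i = 0; i < nt; ++i) {
    kd(i) = kdiag * std::sqrt(FOURPI / area(i));
    w(i) = std::sqrt(area(i) / PI);
  }
  auto apply = [&](const vec& x) -> vec {
    if (Dexp) return (*Dexp) * x;
    vec y = kd % x;
    for (int i = 0; i < nt; ++i) {
      double xi = x(i);
      double acc = 0.0;
      for (int j = i + 1; j < nt; ++j) {
        double dx = tpos(0, i) - tpos(0, j);
        double dy = tpos(1, i) - tpos(1, j);
        double dz = tpos(2, i) - tpos(2, j);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        double inv = dmat_offdiag(d, sphere(i) == sphere(j), w(i), w(j),
                                  kd(i), kd(j));
        acc += inv * x(j);
        y(j) += inv * xi;
      }
      y(i) += acc;
    }
    return y;
  };
  vec q = q0;
  vec r = rhs - apply(q);
  vec z = r / kd;            // Jacobi preconditioner
  vec pdir = z;
  double rz = dot(r, z);
  double rhsn = norm(rhs);
  if (rhsn < 1e-300) { iters = 0; ok = true; return vec(nt, fill::zeros); }
  ok = false;
  for (iters = 0; iters < maxit; ++iters) {
    if (norm(r) / rhsn < tol) { ok = true; break; }
    vec Ap = apply(pdir);
    double alpha = rz / dot(pdir, Ap);
    q += alpha * pdir;
    r -= alpha * Ap;
    z = r / kd;
    double rz2 = dot(r, z);
    pdir = z + (rz2 / rz) * pdir;
    rz = rz2;
  }
  if (norm(r) / rhsn < tol) ok = true;
  return q;
}

// pack one-center density elements (off-diagonal doubled)
static vec pack_density(const mat& P, const std::vector<int>& off,
                        const std::vector<int>& nor, int n1c,
                        const std::vector<int>& col_atom,
                        const std::vector<int>& col_pair) {
  vec pv(n1c);
  for (int c = 0; c < n1c; ++c) {
    int a = col_atom[c], t = col_pair[c];
    int i = off[a] + PIDX[t][0], j = off[a] + PIDX[t][1];
    pv(c) = (i == j) ? P(i, j) : 2.0 * P(i, j);
  }
  return pv;
}

// ---------------------------------------------------------------------------
// SCF driver
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_scf(const arma::mat& coords, const Rcpp::List& plist,
                   const arma::ivec& ielem, int nelec, const Rcpp::List& opts,
                   Rcpp::Nullable<Rcpp::List> pcm_in,
                   Rcpp::Nullable<Rcpp::NumericMatrix> P0_in) {
  std::vector<ElemPar> pars = unpack_params(plist);
  Ints I = build_ints(coords, pars, ielem);

  int max_iter = Rcpp::as<int>(opts["max_iter"]);
  double etol = Rcpp::as<double>(opts["energy_tol"]);
  double ptol = Rcpp::as<double>(opts["density_tol"]);
  bool use_diis = Rcpp::as<bool>(opts["diis"]);
  int diis_size = Rcpp::as<int>(opts["diis_size"]);

  PcmCtx pcm;
  if (pcm_in.isNotNull()) {
    Rcpp::List pl(pcm_in);
    pcm.active = true;
    pcm.tpos = Rcpp::as<mat>(pl["tess_pos"]);    // 3 x nt
    pcm.area = Rcpp::as<vec>(pl["tess_area"]);
    pcm.sphere = Rcpp::as<ivec>(pl["tess_sphere"]);
    pcm.f = Rcpp::as<double>(pl["f"]);
    pcm.kdiag = Rcpp::as<double>(pl["kdiag"]);
    pcm.solver = Rcpp::as<std::string>(pl["solver"]);
    pcm.cg_tol = Rcpp::as<double>(pl["cg_tol"]);
    pcm.T = tessera_integral_matrix(coords, pars, ielem, pcm.tpos,
                                    pcm.col_atom, pcm.col_pair);
    pcm.vnuc = nuclear_potential_vec(coords, pars, ielem, pcm.tpos);
    int nt = pcm.area.n_elem;
    if (pcm.solver == "direct") {
      pcm.D = build_dmat(pcm.tpos, pcm.area, pcm.sphere, pcm.kdiag);
      pcm.Dchol = chol(pcm.D);
      pcm.have_chol = true;
    }
    pcm.q_prev.zeros(nt);
  }

  int nocc = nelec / 2;
  mat P(I.nbf, I.nbf, fill::zeros);
  if (P0_in.isNotNull()) {
    P = Rcpp::as<mat>(P0_in);
  } else {
    double ztot = 0.0;
    for (int a = 0; a < I.nat; ++a) ztot += pars[ielem(a) - 1].zcore;
    double scalef = nelec / ztot;
    for (int a = 0; a < I.nat; ++a) {
      double occ = pars[ielem(a) - 1].zcore / I.nor[a] * scalef;
      for (int k = 0; k < I.nor[a]; ++k) P(I.off[a] + k, I.off[a] + k) = occ;
    }
  }

  std::deque<mat> diis_F;
  std::deque<mat> diis_E;
  double E_prev = 0.0, E = 0.0, gpcm_au = 0.0;
  bool converged = false;
  int iter = 0;
  vec q, V;
  mat Fg, F, C;
  vec eps;

  for (iter = 1; iter <= max_iter; ++iter) {
    Fg = I.H + fock2e(I, pars, ielem, P);
    F = Fg;
    if (pcm.active) {
      vec pv = pack_density(P, I.off, I.nor, pcm.T.n_cols, pcm.col_atom, pcm.col_pair);
      V = pcm.vnuc - pcm.T * pv;
      vec rhs = -pcm.f * V;
      if (pcm.have_chol) {
        q = solve(trimatu(pcm.Dchol), solve(trimatl(pcm.Dchol.t()), rhs));
      } else {
        int cg_it; bool ok;
        q = cg_solve(pcm.tpos, pcm.area, pcm.sphere, pcm.kdiag, rhs,
                     pcm.q_prev, pcm.cg_tol, 2000, cg_it, ok, nullptr);
        if (!ok) Rcpp::stop("C-PCM iterative solver did not converge");
        pcm.q_prev = q;
      }
      vec fv = pcm.T.t() * q;
      for (arma::uword c = 0; c < fv.n_elem; ++c) {
        int a = pcm.col_atom[c], t = pcm.col_pair[c];
        int i = I.off[a] + PIDX[t][0], j = I.off[a] + PIDX[t][1];
        F(i, j) -= fv(c) * EV_PER_HARTREE;
        if (i != j) F(j, i) -= fv(c) * EV_PER_HARTREE;
      }
      gpcm_au = 0.5 * dot(q, V);
    }
    E = 0.5 * accu(P % (I.H + Fg)) + I.enuc + gpcm_au * EV_PER_HARTREE;

    mat err = F * P - P * F;
    double maxerr = abs(err).max();

    mat Fuse = F;
    if (use_diis) {
      diis_F.push_back(F);
      diis_E.push_back(err);
      while ((int)diis_F.size() > diis_size) { diis_F.pop_front(); diis_E.pop_front(); }
      int m = diis_F.size();
      if (m >= 2) {
        mat B(m + 1, m + 1, fill::ones);
        B(m, m) = 0.0;
        for (int i = 0; i < m; ++i)
          for (int j = 0; j < m; ++j) B(i, j) = accu(diis_E[i] % diis_E[j]);
        vec rhs(m + 1, fill::zeros);
        rhs(m) = 1.0;
        vec cvec;
        bool okc = solve(cvec, B, rhs, solve_opts::no_approx);
        if (okc && cvec.is_finite()) {
          Fuse.zeros();
          for (int i = 0; i < m; ++i) Fuse += cvec(i) * diis_F[i];
        } else {
          diis_F.pop_front(); diis_E.pop_front();
        }
      }
    }

    eig_sym(eps, C, Fuse);
    mat Pnew = 2.0 * C.cols(0, nocc - 1) * C.cols(0, nocc - 1).t();
    double dP = abs(Pnew - P).max();
    if (!use_diis && iter > 1) Pnew = 0.5 * (Pnew + P);
    P = Pnew;
    if (iter > 1 && std::fabs(E - E_prev) < etol && dP < ptol && maxerr < 1e-3) {
      converged = true;
      break;
    }
    E_prev = E;
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("P") = P, Rcpp::Named("F") = F,
      Rcpp::Named("orbital_energies") = eps,
      Rcpp::Named("electronic_energy") = E - I.enuc - gpcm_au * EV_PER_HARTREE,
      Rcpp::Named("core_repulsion_energy") = I.enuc,
      Rcpp::Named("total_energy") = E,
      Rcpp::Named("gpcm_au") = gpcm_au,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = iter);
  if (pcm.active) {
    out["q"] = q;
    out["V"] = V;
  }
  return out;
}

// gas-phase semi-empirical energy expression evaluated at fixed density (eV)
// [[Rcpp::export]]
double cpp_energy_fixed_density(const arma::mat& coords, const Rcpp::List& plist,
                                const arma::ivec& ielem, const arma::mat& P) {
  std::vector<ElemPar> pars = unpack_params(plist);
  Ints I = build_ints(coords, pars, ielem);
  mat Fg = I.H + fock2e(I, pars, ielem, P);
  return 0.5 * accu(P % (I.H + Fg)) + I.enuc;
}

// two-center energy contribution of a single pair at fixed density
static double pair_energy(const ElemPar& pa, const ElemPar& pb, const vec3& rab,
                          const mat& P, int oa, int ob, int na, int nb) {
  double R = norm(rab);
  std::vector<double> w(256);
  pair_w_tensor(pa, pb, rab, w.data());
  vec e1a, e1b;
  pair_core_attraction(pa, pb, rab, e1a, e1b);
  mat S = overlap_block(pa, pb, rab);
  double e = core_core_pair(pa, pb, R);
  int nta = (na == 4) ? 10 : 1, ntb = (nb == 4) ? 10 : 1;
  for (int t = 0; t < nta; ++t) {
    int i = PIDX[t][0], j = PIDX[t][1];
    e += e1a(t) * ((i == j) ? P(oa + i, oa + j) : 2.0 * P(oa + i, oa + j));
  }
  for (int t = 0; t < ntb; ++t) {
    int i = PIDX[t][0], j = PIDX[t][1];
    e += e1b(t) * ((i == j) ? P(ob + i, ob + j) : 2.0 * P(ob + i, ob + j));
  }
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < nb; ++k) {
      double bi = (i == 0) ? pa.betas : pa.betap;
      double bk = (k == 0) ? pb.betas : pb.betap;
      e += 2.0 * P(oa + i, ob + k) * 0.5 * (bi + bk) * S(i, k);
    }
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j)
      for (int k = 0; k < nb; ++k)
        for (int l = 0; l < nb; ++l) {
          double wv = w[((i * 4 + j) * 4 + k) * 4 + l];
          e += P(oa + i, oa + j) * P(ob + k, ob + l) * wv;
          e -= 0.5 * P(oa + i, ob + k) * P(oa + j, ob + l) * wv;
        }
  return e;
}

// numerical (central-difference) gradient of the gas-phase energy expression
// at fixed density; returns hartree/bohr
// [[Rcpp::export]]
arma::vec cpp_core_gradient_fd(const arma::mat& coords, const Rcpp::List& plist,
                               const arma::ivec& ielem, const arma::mat& P,
                               double h) {
  std::vector<ElemPar> pars = unpack_params(plist);
  int nat = ielem.n_elem;
  std::vector<int> off, nor;
  int nbf;
  basis_layout(pars, ielem, off, nor, nbf);
  vec g(3 * nat, fill::zeros);

  auto atom_pair_energy = [&](const mat& crd, int a) {
    double e = 0.0;
    const ElemPar& pa = pars[ielem(a) - 1];
    for (int b = 0; b < nat; ++b) {
      if (b == a) continue;
      const ElemPar& pb = pars[ielem(b) - 1];
      if (b > a)
        e += pair_energy(pa, pb, vec3(crd.col(b) - crd.col(a)), P,
                         off[a], off[b], nor[a], nor[b]);
      else
        e += pair_energy(pb, pa, vec3(crd.col(a) - crd.col(b)), P,
                         off[b], off[a], nor[b], nor[a]);
    }
    return e;
  };

  mat crd = coords;
  for (int a = 0; a < nat; ++a)
    for (int c = 0; c < 3; ++c) {
      crd(c, a) = coords(c, a) + h;
      double ep = atom_pair_energy(crd, a);
      crd(c, a) = coords(c, a) - h;
      double em = atom_pair_energy(crd, a);
      crd(c, a) = coords(c, a);
      g(3 * a + c) = (ep - em) / (2.0 * h) / EV_PER_HARTREE;
    }
  return g;
}

// ---------------------------------------------------------------------------
// small exported helpers for unit tests and the R-level module surface
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_build_hcore(const arma::mat& coords, const Rcpp::List& plist,
                           const arma::ivec& ielem) {
  std::vector<ElemPar> pars = unpack_params(plist);
  Ints I = build_ints(coords, pars, ielem);
  return Rcpp::List::create(Rcpp::Named("H") = I.H,
                            Rcpp::Named("enuc") = I.enuc,
                            Rcpp::Named("nbf") = I.nbf);
}

// [[Rcpp::export]]
arma::mat cpp_pair_repulsion(const Rcpp::List& parA, const Rcpp::List& parB,
                             const arma::vec& rab) {
  Rcpp::List pl = Rcpp::List::create(parA, parB);
  std::vector<ElemPar> pars = unpack_params(pl);
  return pair_repulsion_block(pars[0], pars[1], vec3(rab));
}

// [[Rcpp::export]]
arma::mat cpp_overlap_block(const Rcpp::List& parA, const Rcpp::List& parB,
                            const arma::vec& rab) {
  Rcpp::List pl = Rcpp::List::create(parA, parB);
  std::vector<ElemPar> pars = unpack_params(pl);
  return overlap_block(pars[0], pars[1], vec3(rab));
}

// [[Rcpp::export]]
double cpp_sto_overlap_local(int n1, int l1, double z1, int n2, int l2,
                             double z2, double R, int m) {
  return sto_overlap_local(n1, l1, z1, n2, l2, z2, R, m);
}

// [[Rcpp::export]]
double cpp_core_core(const Rcpp::List& parA, const Rcpp::List& parB, double r) {
  Rcpp::List pl = Rcpp::List::create(parA, parB);
  std::vector<ElemPar> pars = unpack_params(pl);
  return core_core_pair(pars[0], pars[1], r);
}

// [[Rcpp::export]]
arma::mat cpp_fock2e(const arma::mat& coords, const Rcpp::List& plist,
                     const arma::ivec& ielem, const arma::mat& P) {
  std::vector<ElemPar> pars = unpack_params(plist);
  Ints I = build_ints(coords, pars, ielem);
  return fock2e(I, pars, ielem, P);
}

// [[Rcpp::export]]
arma::mat cpp_build_dmatrix(const arma::mat& tpos, const arma::vec& area,
                            const arma::ivec& sphere, double kdiag) {
  int nt = area.n_elem;
  for (int i = 0; i < nt; ++i)
    for (int j = i + 1; j < nt; ++j)
      if (norm(tpos.col(i) - tpos.col(j)) < 1e-8)
        Rcpp::stop("degenerate cavity: coincident tesserae");
  return build_dmat(tpos, area, sphere, kdiag);
}

// [[Rcpp::export]]
Rcpp::List cpp_cg_asc(const arma::mat& tpos, const arma::vec& area,
                      const arma::ivec& sphere, double kdiag,
                      const arma::vec& rhs, const arma::vec& q0,
                      double tol, int maxit) {
  int iters = 0;
  bool ok = false;
  vec q = cg_solve(tpos, area, sphere, kdiag, rhs, q0, tol, maxit, iters, ok, nullptr);
  return Rcpp::List::create(Rcpp::Named("q") = q, Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = ok);
}
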