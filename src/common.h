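#pragma once
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

// Physical constants follow the conventions the NDDO parameterizations were
// fitted with (MOPAC-era values), so that published heats of formation are
// reproduced to the printed digit.
constexpr double EV_PER_HARTREE = 27.21;
constexpr double ANGSTROM_PER_BOHR = 0.529167;
constexpr double KCAL_PER_EV = 23.061;

struct ElemPar {
  int z = 0;            // atomic number
  double zcore = 0.0;   // valence core charge
  int norb = 1;         // 1 (s) or 4 (s,p)
  int npq = 1;          // principal quantum number of valence shell
  double uss = 0, upp = 0;         // eV
  double zs = 0, zp = 0;           // bohr^-1
  double betas = 0, betap = 0;     // eV
  double alpha = 0;                // A^-1
  double gss = 0, gsp = 0, gpp = 0, gp2 = 0, hsp = 0; // eV
  arma::mat gauss;                 // k x 3: K (eV), L (A^-2), M (A)
  double dd = 0, qq = 0;           // multipole charge separations, bohr
  double rho0 = 0, rho1 = 0, rho2 = 0; // Klopman-Ohno additive terms, bohr
  double eisol = 0;                // eV
  double eheat = 0;                // kcal/mol
};

std::vector<ElemPar> unpack_params(const Rcpp::List& plist);

// C-PCM off-diagonal element (nddo.cpp): exact 1/d with a safety cap for
// same-sphere pairs, tessera-size damped for inter-sphere pairs
double dmat_offdiag(double d, bool same_sphere, double wi, double wj,
                    double kdi, double kdj);

// pair-block machinery (nddo.cpp)
arma::mat pair_repulsion_block(const ElemPar& pa, const ElemPar& pb,
                               const arma::vec3& rab);
void pair_core_attraction(const ElemPar& pa, const ElemPar& pb,
                          const arma::vec3& rab,
                          arma::vec& e1a, arma::vec& e1b);
double core_core_pair(const ElemPar& pa, const ElemPar& pb, double r_bohr);
arma::mat overlap_block(const ElemPar& pa, const ElemPar& pb,
                        const arma::vec3& rab);
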