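---
title: "Semi-empirical electronic structure with conductor-like continuum solvation: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-empirical electronic structure with conductor-like continuum solvation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sepcm` couples an NDDO semi-empirical electronic-structure engine (MNDO, AM1,
PM3; elements H, C, N, O) to the conductor-like polarizable continuum model
(C-PCM) of aqueous solvation. This vignette explains the models, the numerical
choices behind them, and what the shipped benchmark can and cannot show.

## The gas-phase NDDO model

MNDO-family methods describe the valence electrons in a minimal Slater basis
(1s on H; 2s,2p on C, N, O) under the neglect-of-diatomic-differential-overlap
approximation. The ingredients are:

* **One-center terms** — empirical orbital energies `U_ss`, `U_pp` and
  one-center two-electron integrals `g_ss, g_sp, g_pp, g_p2, h_sp` (eV).
* **Resonance terms** — `H_{mu nu} = 1/2 (beta_mu + beta_nu) S_{mu nu}` with
  exact Slater overlaps, computed here in prolate spheroidal coordinates via
  the classical `A_k`/`B_k` auxiliary integrals (machine-precision analytic
  values; `B_k` switches to a power series near equal exponents).
* **Two-center two-electron integrals** — each one-center orbital-pair charge
  distribution is represented by a point-multipole configuration: a monopole,
  a dipole of charges ±e/2 separated by the empirical length `D1`, and linear
  (separation `2 D2`) or square (`D2`) quadrupoles. Configuration pairs
  interact through the Klopman–Ohno form
  `sum q_i q_j / sqrt(r_ij^2 + (rho_l(A) + rho_l'(B))^2)`,
  which interpolates between `1/R` at long range and the correct one-center
  integrals at `R = 0`. `D1`, `D2` follow from the Slater exponents; the
  additive terms `rho_0, rho_1, rho_2` are solved (by `uniroot`) so the
  one-center limits reproduce `g_ss`, `h_sp` and `(g_pp - g_p2)/2`.
* **Core–core repulsion** — screened monopole repulsion
  `Z_A Z_B (s_A s_A | s_B s_B) (1 + e^{-alpha_A R} + e^{-alpha_B R})`, with
  the distance-weighted exponential for N–H and O–H pairs, plus the AM1/PM3
  Gaussian corrections.

Derived quantities are recomputed from the published primitive constants
rather than tabulated: the atomic reference energies `E_isol` follow from the
standard ground-state occupation coupling (they reproduce the canonical
values, e.g. −111.229917 eV for PM3 carbon, exactly), and physical constants
use the conventions the parameterizations were fitted with
(27.21 eV/hartree, 0.529167 Å/bohr, 23.061 kcal/mol/eV). With these choices
the engine reproduces published PM3 heats of formation (H₂, CH₄, NH₃, H₂O,
CH₃OH) to better than 0.1 kcal/mol at tightly optimized geometries — the
strongest end-to-end check available without a second semi-empirical code in
the test environment.

The SCF is restricted closed-shell (every species in the shipped benchmark is
a closed-shell cation), converged on both the total energy (1e-7 eV) and the
density (1e-6), with DIIS (error vector `FP − PF`, subspace 8) on by default;
without DIIS a simple 50/50 damping is used. The initial guess distributes
the valence electrons uniformly over each atom's orbitals, scaled for the net
charge. Non-convergence is a flagged outcome, not an exception.

## The cavity

The solute cavity is the union of atomic spheres (Bondi radii × 1.2 by
default, both configurable — see "Limitations"). Each sphere carries 60, 240
or 960 triangular tesserae obtained by subdividing a pentakis dodecahedron;
a tessera's representative point is the projected center of its triangle, so
it *rides rigidly* with its parent atom. Tesserae whose representative point
falls inside another sphere are removed; partially covered tesserae keep
their exposed area, computed exactly by the Gauss–Bonnet theorem on the
clipped spherical polygon (geodesic edges plus intersection-circle arcs).
For an isolated sphere the tessellation therefore closes to `4 pi R^2` at
machine precision, and two-sphere cavities match the analytic union area to
better than 1.5% at 960 tesserae per sphere.

The subdivision polyhedron is seeded in a principal-axis frame built from
index-weighted atomic coordinates. The index weighting (`mass × (1+0.001 i)`)
breaks the axis degeneracy of symmetric tops such as NH₄⁺ deterministically,
so the tessellation co-rotates exactly with the molecule and solvation
energies are frame invariant. Finite-difference displacements reuse the
reference frame explicitly so tesserae can be matched across rebuilds by
their (sphere, triangle) key.

## C-PCM electrostatics

Apparent surface charges solve `D q = -f V` with
`D_ii = 1.0694 sqrt(4 pi / a_i)` and off-diagonal inverse tessera distances;
`f(eps) = (eps-1)/eps` (the `(eps-1)/(eps+0.5)` variant is available; for
water they differ by < 0.7%). The surface potential `V` carries the valence
core charges and the NDDO electronic term
`-sum P_{mu nu} <mu nu>_i`, where `<mu nu>_i` are the same point-multipole
interaction integrals as above evaluated against a unit charge at the
tessera, with the additive `rho` terms set to zero and every point-charge
distance floored at 0.1 bohr (the bare multipole sums would otherwise be
singular in the near field; the clamp is logged and its derivative branch is
zero). The integrals are evaluated in a local frame whose z axis points at
the tessera and rotated onto the molecular frame with the direction cosines;
only four unique local potentials are needed (ss, s-pσ, pσpσ, pπpπ).

Two numerical safeguards matter in practice:

* **Seam damping.** Representative points of cut tesserae on different
  spheres can nearly coincide along sphere-intersection seams. A bare `1/d`
  coupling there destroys the positive definiteness of `D`. Inter-sphere
  couplings are therefore damped on the tessera size scale,
  `D_ij = 1/sqrt(d^2 + w_i w_j)` with `w = sqrt(a/pi)`; same-sphere pairs
  (rigid, never degenerate) keep the exact form. Single-sphere results —
  the Born model, Gauss's law — are untouched: a 960-tessera sphere of
  radius 2 Å reproduces the Born energy to 0.01%.
* **Solver choice.** The linear system is solved by Cholesky factorization
  (cached across SCF iterations) up to 4000 tesserae and by matrix-free
  Jacobi-preconditioned conjugate gradients (residual 1e-8, warm-started
  from the previous iteration) beyond; the two agree to 1e-6 per charge.

The PCM one-electron operator `F_{mu nu} = -sum_i q_i <mu nu>_i` is rebuilt
from the current density at every SCF iteration (fully coupled), and the
total energy adds the variational interaction free energy
`dG_el = 1/2 sum q_i V_i`. The reported solvation magnitude of the benchmark
is the total-energy difference
`-(E_PCM(solvated geometry) - E_gas(gas geometry))`, i.e. it includes solute
electronic and geometric relaxation; the bare `dG_el` at the final point is
reported alongside for users who want the interaction term only.

## Gradients

The gradient splits by how each term is best evaluated:

* the **core semi-empirical gradient** is numerical: central differences of
  the gas-phase energy expression at the fixed converged density (valid by
  the variational principle; only atom-pair terms involving the displaced
  atom are recomputed). The default step is 1e-3 bohr; halving it changes
  components by < 1e-5 hartree/bohr.
* the **solvent-field terms** `q^T dV/dx` (nuclear and electronic, with
  tesserae riding rigidly on their parent spheres) and the inter-sphere
  position dependence of `q^T D q` are analytic, by the chain rule through
  the local-frame potentials and direction cosines.
* the **tessera-area term** — the area dependence of the `D` diagonal and of
  the seam damping — is evaluated by central differences of deterministic
  cavity rebuilds at fixed reference positions. A tessera appearing or
  vanishing inside the stencil is a genuine tessellation discontinuity: the
  step is halved up to three times, then the component is flagged (never
  smoothed).

The assembled gradient matches full central finite differences of the total
PCM energy to ~1e-7 hartree/bohr away from tessellation events, and to the
1e-4 acceptance tolerance across all twenty benchmark fixtures.

## Optimization, Hessians, frequencies

Geometries are minimized by Cartesian BFGS (unit initial inverse Hessian,
0.3 bohr step cap, backtracking line search) to a maximum gradient component
of 5e-4 hartree/bohr within 100 steps. Because tessera removal puts small
walls (typically 0.05–0.2 kcal/mol, measured directly with finite-difference
probes) on the PCM energy surface, the PCM line search accepts steps within
an 0.01 eV uphill tolerance; convergence is still judged on the gradient and
the lowest-energy geometry seen is returned. A line search that collapses to
zero step twice in a row sets the *stall* flag and terminates with a usable
geometry — under the study defaults this happens for four of the twenty
benchmark cations (ammonium, methylammonium, ethyloxonium and the compact
tert-butylammonium), the same small-cavity regime in which reference
implementations of this model report stalled optimizations; the other
sixteen converge. A `hessian_update = FALSE`
switch mirrors the classical skip-update workaround for such stalls.

Hessians are double differences of gradients (0.01 bohr displacements,
symmetrized; the pre-symmetrization asymmetry is itself a consistency
diagnostic). Frequencies come from the mass-weighted Hessian after
projecting the six (five for linear geometries) rigid-body vectors; negative
eigenvalues are reported as negative wavenumbers with an imaginary-mode
count. The solvation-induced frequency shift statistic pairs the solvated
and gas-phase spectra by ascending index — no mode-tracking is attempted —
and excludes imaginary modes, keeping their counts attached; a count
mismatch after exclusion is an error the caller must resolve.

## The benchmark and what it shows

`run_study()` executes, for twenty ammonium- and oxonium-type cations
specified by SMILES (shipped as pre-generated 3D structures), the three-stage
pipeline: gas-phase optimization, C-PCM re-optimization at 60 tesserae per
sphere, and a single point at 960 tesserae per sphere, in water
(ε = 78.39). Literature reference values are embedded for deviation
reporting, and table-wise mean signed deviations are aggregated over
converged entries.

Under the default radii (Bondi × 1.2) the computed magnitudes track the
literature values with a systematic offset of about −2.5 kcal/mol against
the older D-PCM reference data and about −1 kcal/mol against more recent
conductor-like results. Two caveats bound what this agreement means:

* the cavity radii driving these numbers are the dominant unknown when
  comparing across codes — a few percent change in radii moves cation
  solvation energies by 1–2 kcal/mol, which is why the radii table and scale
  are explicit configuration, not constants;
* the fixture geometries are one conformer per molecule. For flexible chains
  (n-butylammonium is the clearest case) the gas- and solvent-phase
  conformer choice can move the reported magnitude by ~1 kcal/mol.

The shipped fixtures are synthetic in the sense that any chemically
reasonable starting structure suffices — every reported quantity follows
geometry optimization — but they do not probe conformational ensembles,
nonelectrostatic (cavitation/dispersion) contributions, or explicit
solute–water hydrogen bonding; passing the benchmark says the electrostatic
continuum response and its gradients are implemented correctly, not that the
physical model captures everything about aqueous solvation.

## Problem sizes and determinism

The study runs at its published settings (60/960 tesserae per sphere,
OPTTOL 5e-4, ≤100 steps); the whole twenty-molecule benchmark completes in
a few minutes on one CPU. Everything downstream of the fixture files is
deterministic: identical configurations produce bit-identical reports, and
the `random_seed` field in the configuration is provenance only.

## Known limitations

* Elements H, C, N, O; restricted closed-shell references only; no
  d-orbitals, open shells or excited states.
* GEPOL-style center-removal makes the PCM energy surface piecewise smooth;
  optimizations of very small or very crowded cavities can stall (flagged,
  never silent). Smoothed tessellations would remove the walls at the cost
  of changing the model; this package deliberately keeps the discontinuities
  observable.
* The cavity term of the gradient is numerical (central differences of
  areas); a closed-form Gauss–Bonnet area derivative is not implemented.
* Nonelectrostatic solvation terms are out of scope; the reported quantity
  is electrostatic only.
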