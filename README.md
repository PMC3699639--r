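# sepcm — semi-empirical NDDO electronic structure with C-PCM solvation

`sepcm` is a self-contained quantum-chemistry engine for R. It implements the
MNDO, AM1 and PM3 semi-empirical methods (elements H, C, N, O; restricted
closed shell) and couples them to the conductor-like polarizable continuum
model (C-PCM) of solvation, for people who want reproducible aqueous
solvation free energies, solvated geometries and vibrational frequencies of
small organic ions without an external quantum-chemistry installation.

The physics, end to end:

* **NDDO SCF** — exact Slater overlaps (spheroidal A/B auxiliary integrals),
  two-center two-electron integrals in the point-multipole representation
  with Klopman–Ohno damping, MNDO-type screened core–core repulsion with
  AM1/PM3 Gaussian corrections, DIIS-accelerated SCF, heats of formation.
* **Cavity** — interlocked atomic spheres (Bondi radii × 1.2 by default),
  each tessellated with 60/240/960 triangles from a subdivided pentakis
  dodecahedron; exposed areas of cut tesserae from the Gauss–Bonnet theorem
  on the clipped spherical polygons.
* **C-PCM** — apparent surface charges from `D q = −f(ε) V` with
  `f = (ε−1)/ε`, `D_ii = 1.0694·sqrt(4π/a_i)`; solute potential from the
  valence cores and the NDDO density; the surface term enters the Fock
  matrix every SCF cycle and the energy as `ΔG_el = ½ Σ q_i V_i`.
* **Gradients** — numerical core gradient at fixed density plus analytic
  solvent-field derivatives (`q·∂V/∂x`, tesserae riding their spheres) and a
  numerical tessera-area term; validated against full finite differences.
* **Optimization / frequencies** — Cartesian BFGS to a 5·10⁻⁴ hartree/bohr
  max-gradient threshold, double-difference Hessians, rigid-body-projected
  harmonic frequencies, and a sorted-pair mean absolute deviation between
  solvated and gas-phase spectra.
* **Benchmark driver** — a twenty-cation aqueous solvation study
  (gas-phase optimization → C-PCM re-optimization at 60 tesserae/sphere →
  960 tesserae/sphere single point) with embedded literature reference
  values and CSV/JSON/markdown reports.

## A worked example

Solvation free energy of methylammonium in water with PM3:

```r
library(sepcm)

mol <- load_fixture("A2")          # CH3NH3+, shipped 3D structure
res <- solvation_free_energy(mol, method = "PM3", verbose = TRUE)
#> stage 1: gas-phase optimization
#> stage 2: PCM re-optimization ( 60  tesserae/sphere)
#> stage 3: PCM single point ( 960  tesserae/sphere)
res$magnitude
#> [1] 71.43226
res$dG_el
#> [1] -72.20799
```

`magnitude` (71.4 kcal/mol) is the electrostatic solvation free energy
reported positively for cations: gas-phase total energy at the gas-optimized
geometry minus the solvated total energy at the C-PCM-optimized geometry, so
it includes solute relaxation. `dG_el` (−72.2 kcal/mol) is the bare
charge–potential interaction free energy `½Σq·V` at the final point. The
corresponding literature values are 73.7 (older D-PCM reference data) and
72.6 kcal/mol (conductor-like PCM); the ~1 kcal/mol gap is dominated by the
cavity radii, which that literature does not print — `radii_table` and
`radii_scale` are therefore explicit arguments.

The full benchmark, with per-molecule deviations and table averages:

```r
rep <- run_study(study_config(), verbose = TRUE)
print(rep)
write_report(rep, dir = "results")   # CSV, JSON, markdown
```

Lower-level pieces are exported individually (`scf()`, `tessellate_gepol()`,
`solve_asc()`, `total_gradient()`, `optimize_geometry()`, `frequencies()`,
…) and a thin command-line driver ships in `inst/scripts/sepcm`
(`sepcm energy|opt|freq|solvate|study`).

## Scope

Elements H, C, N, O; closed-shell species; electrostatic solvation only (no
cavitation/dispersion terms). See the methods vignette
(`vignettes/sepcm-methods.Rmd`) for the model details, the numerical
safeguards around the moving tessellation, and known limitations.
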