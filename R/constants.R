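# Physical constants, kept at the values the MNDO-family parameterizations
# were fitted with so that published heats of formation are reproduced.
EV_PER_HARTREE <- 27.21
ANGSTROM_PER_BOHR <- 0.529167
KCAL_PER_EV <- 23.061
KCAL_PER_HARTREE <- EV_PER_HARTREE * KCAL_PER_EV
WAVENUMBER_PER_AU <- 219474.63
AMU_PER_ELECTRON_MASS <- 1 / 1822.888486

# most-abundant-isotope masses (amu), used for mass-weighted Hessians
ATOMIC_MASSES <- c(H = 1.007825, C = 12.000000, N = 14.003074, O = 15.994915)

# Bondi van der Waals radii (Angstrom)
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52)

SUPPORTED_ELEMENTS <- c("H", "C", "N", "O")

angstrom_to_bohr <- function(x) x / ANGSTROM_PER_BOHR
bohr_to_angstrom <- function(x) x * ANGSTROM_PER_BOHR
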