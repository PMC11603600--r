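# Physical constants, CODATA 2018.  Every other file takes its numbers from
# `.pc`; no literal physical constants appear elsewhere in the package.

.pc <- local({
  h   <- 6.62607015e-34        # Planck constant, J s (exact)
  kB  <- 1.380649e-23          # Boltzmann constant, J K^-1 (exact)
  N_A <- 6.02214076e23         # Avogadro constant, mol^-1 (exact)
  c_cm <- 2.99792458e10        # speed of light, cm s^-1 (exact)
  amu <- 1.66053906660e-27     # atomic mass constant, kg
  hartree_J <- 4.3597447222071e-18  # hartree, J
  cal_J <- 4.184               # thermochemical calorie, J (exact)
  atm_Pa <- 101325             # standard atmosphere, Pa (exact)

  R_J <- kB * N_A              # gas constant, J mol^-1 K^-1

  list(
    h = h, kB = kB, N_A = N_A, c_cm = c_cm,
    amu_kg = amu,
    angstrom_m = 1e-10,
    bohr_angstrom = 0.529177210903,
    hartree_J = hartree_J,
    hartree_kcalmol = hartree_J * N_A / (cal_J * 1000),
    wavenumber_J = h * c_cm,             # E(J) per cm^-1
    cal_J = cal_J,
    atm_Pa = atm_Pa,
    R_J = R_J,                           # J mol^-1 K^-1
    R_cal = R_J / cal_J,                 # cal mol^-1 K^-1
    R_kcal = R_J / (cal_J * 1000),       # kcal mol^-1 K^-1
    R_Latm = R_J / atm_Pa * 1000,        # L atm mol^-1 K^-1
    P_standard_atm = 1,                  # standard pressure, atm
    c_standard_M = 1                     # standard concentration, mol L^-1
  )
})

#' Physical constants used throughout the package
#'
#' Returns the package's pinned table of physical constants (CODATA 2018;
#' the SI-exact defining constants are exact) together with the derived unit
#' conversion factors.  All internal computations draw on this single table,
#' which makes results bit-reproducible across platforms.
#'
#' @return A data frame with columns `name`, `value` and `unit`.
#' @examples
#' vtst_constants()
#' @export
vtst_constants <- function() {
  units <- c(
    h = "J s", kB = "J K-1", N_A = "mol-1", c_cm = "cm s-1",
    amu_kg = "kg", angstrom_m = "m", bohr_angstrom = "Angstrom",
    hartree_J = "J", hartree_kcalmol = "kcal mol-1",
    wavenumber_J = "J per cm-1", cal_J = "J",
    atm_Pa = "Pa", R_J = "J mol-1 K-1", R_cal = "cal mol-1 K-1",
    R_kcal = "kcal mol-1 K-1", R_Latm = "L atm mol-1 K-1",
    P_standard_atm = "atm", c_standard_M = "mol L-1"
  )
  data.frame(
    name = names(.pc),
    value = unname(unlist(.pc)),
    unit = unname(units[names(.pc)]),
    stringsAsFactors = FALSE
  )
}
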