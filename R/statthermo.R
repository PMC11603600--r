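# Ideal-gas statistical thermodynamics: rigid-rotor / harmonic-oscillator
# component partition functions, state functions from ln Q, and the
# 1 atm -> 1 M standard-state bookkeeping for activation quantities.
#
# Conventions:
#   * vibrational partition functions are bottom-of-well referenced, so the
#     zero-point energy emerges from q rather than being added separately;
#   * the translational q uses the per-molecule volume kB*T/P, which makes
#     G = E_elec - RT ln Q the standard-state chemical potential directly;
#   * rotational symmetry numbers are NOT folded into q by default; symmetry
#     enters the rate constant once, through the reaction symmetry factor.

#' Thermodynamic conditions
#'
#' @param T Temperature in K (scalar, > 0).
#' @param P Pressure in atm.
#' @return List with `T`, `P` and the ideal-gas molar volume `V_m` (L/mol).
#' @export
thermo_conditions <- function(T = 298.15, P = 1) {
  stopifnot(is.numeric(T), length(T) == 1L, T > 0, P > 0)
  list(T = T, P = P, V_m = .pc$R_Latm * T / P)
}

#' Translational partition function
#'
#' `(2 pi m kB T / h^2)^{3/2} * V` for one molecule of mass `m` in volume
#' `V`.
#'
#' @param mass Molecular mass in amu.
#' @param T Temperature in K.
#' @param V Volume in m^3 (per molecule; `kB*T/P` gives the standard-state
#'   value used by [thermo_from_Q()]).
#' @return Dimensionless partition function.
#' @export
q_translational <- function(mass, T, V) {
  stopifnot(mass > 0, T > 0, V > 0)
  m <- mass * .pc$amu_kg
  (2 * pi * m * .pc$kB * T / .pc$h^2)^1.5 * V
}

#' Principal moments of inertia
#'
#' Moments of inertia about the principal axes, from per-atom masses and
#' Cartesian coordinates.
#'
#' @param record A [species_record()].
#' @return Numeric vector of the three principal moments in amu Angstrom^2,
#'   sorted increasingly.
#' @export
principal_moments <- function(record) {
  a <- record$atoms
  m <- a$mass
  com <- c(sum(m * a$x), sum(m * a$y), sum(m * a$z)) / sum(m)
  x <- a$x - com[1]; y <- a$y - com[2]; z <- a$z - com[3]
  I <- matrix(c(
    sum(m * (y^2 + z^2)), -sum(m * x * y),      -sum(m * x * z),
    -sum(m * x * y),      sum(m * (x^2 + z^2)), -sum(m * y * z),
    -sum(m * x * z),      -sum(m * y * z),      sum(m * (x^2 + y^2))),
    nrow = 3, byrow = TRUE)
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Rigid-rotor rotational partition function
#'
#' Linear species: `8 pi^2 I kB T / (sigma h^2)`.  Nonlinear:
#' `sqrt(pi)/sigma * prod_i sqrt(8 pi^2 I_i kB T / h^2)` over the three
#' principal moments.  With `include_sigma = FALSE` (the package default in
#' rate computations) the symmetry number is omitted; reaction symmetry is
#' then applied once via [symmetry_factor()].
#'
#' @param record A [species_record()].
#' @param T Temperature in K.
#' @param include_sigma Divide by the rotational symmetry number?
#' @return Dimensionless partition function (1 for a single atom, with a
#'   warning).
#' @export
q_rotational <- function(record, T, include_sigma = FALSE) {
  if (nrow(record$atoms) < 2L) {
    warning("single atom: rotational partition function is 1")
    return(1)
  }
  mom <- principal_moments(record) * .pc$amu_kg * .pc$angstrom_m^2
  sig <- if (include_sigma) record$sigma else 1
  fac <- 8 * pi^2 * .pc$kB * T / .pc$h^2
  if (record$linear) {
    I <- mom[3]                       # the two nonzero moments are equal
    if (I <= 0) stop("zero moment of inertia for a claimed-linear species")
    fac * I / sig
  } else {
    if (any(mom <= 0))
      stop("zero principal moment for a claimed-nonlinear species")
    sqrt(pi) / sig * prod(sqrt(fac * mom))
  }
}

#' Harmonic-oscillator vibrational partition function
#'
#' Product over modes of `exp(-x_i/2) / (1 - exp(-x_i))` with
#' `x_i = h c nu_i / (kB T)`; bottom-of-well referenced, so the zero-point
#' energy is carried inside q.
#'
#' @param frequencies Wavenumbers in cm^-1, all positive (imaginary and
#'   torsion-replaced modes must already be removed).
#' @param T Temperature in K.
#' @return Dimensionless partition function (1 for an empty list).
#' @export
q_vibrational_HO <- function(frequencies, T) {
  if (!length(frequencies)) return(1)
  bad <- which(frequencies <= 0)
  if (length(bad))
    stop("nonpositive frequency at mode index ", paste(bad, collapse = ", "))
  x <- .pc$wavenumber_J * frequencies / (.pc$kB * T)
  prod(exp(-x / 2) / (1 - exp(-x)))
}

#' Electronic partition function
#'
#' `sum_i g_i exp(-eps_i / kB T)` over electronic levels.
#'
#' @param levels Two-column matrix: degeneracy, level energy in cm^-1
#'   (ground level at 0).
#' @param T Temperature in K.
#' @return Dimensionless partition function.
#' @export
q_electronic <- function(levels, T) {
  levels <- as.matrix(levels)
  sum(levels[, 1] * exp(-.pc$wavenumber_J * levels[, 2] / (.pc$kB * T)))
}

# ln q and d ln q / dT for each component, volume held fixed in the
# derivative (so U excludes the PV term and H = U + RT holds for totals).
.lnq_components <- function(record, cond, hr_model = "HO",
                            include_sigma = FALSE) {
  T <- cond$T
  V <- .pc$kB * T / (cond$P * .pc$atm_Pa)    # per-molecule volume, m^3
  mass <- sum(record$atoms$mass)
  lnq_t <- log(q_translational(mass, T, V))
  dln_t <- 3 / (2 * T)

  if (nrow(record$atoms) >= 2L) {
    lnq_r <- log(q_rotational(record, T, include_sigma))
    dln_r <- if (record$linear) 1 / T else 3 / (2 * T)
  } else {
    lnq_r <- 0; dln_r <- 0
  }

  vib <- .vib_lnq(record, T, model = hr_model)

  qe <- q_electronic(record$levels, T)
  eps <- .pc$wavenumber_J * record$levels[, 2]
  mean_e <- sum(record$levels[, 1] * eps * exp(-eps / (.pc$kB * T))) / qe
  dln_e <- mean_e / (.pc$kB * T^2)

  list(trans = c(lnq_t, dln_t), rot = c(lnq_r, dln_r),
       vib = c(vib$lnq, vib$dlnq), elec = c(log(qe), dln_e),
       lnQ = lnq_t + lnq_r + vib$lnq + log(qe),
       dlnQ = dln_t + dln_r + vib$dlnq + dln_e)
}

#' Thermodynamic state functions from the canonical partition function
#'
#' Assembles `U`, `H`, `S`, `G` and the zero-point energy for one species at
#' the given conditions from the factorized partition function
#' `Q = q_trans q_rot q_vib q_elec`.  With the package conventions,
#' `U = RT^2 dlnQ/dT + E_elec`, `H = U + RT`,
#' `S = R (ln Q + T dlnQ/dT + 1)` (Sackur-Tetrode consistent), and
#' `G = H - T S = E_elec - RT ln Q`.
#'
#' @param record A [species_record()].
#' @param cond A [thermo_conditions()] object.
#' @param hr_model Vibrational model for torsional modes: `"HO"`, `"PG"`
#'   or `"AS"` (see [compose_vibrational()]).
#' @param include_sigma Fold the rotational symmetry number into q_rot?
#'   Off by default; symmetry is applied once in the rate expression.
#' @return List of class `thermo_state`: `T`, `ZPE`, `U`, `H`, `G`
#'   (kcal/mol, electronic energy included), `S` (cal/mol/K), `lnQ`,
#'   `dlnQ_dT`, per-component breakdown, and the standard state.
#' @export
thermo_from_Q <- function(record, cond = thermo_conditions(),
                          hr_model = c("HO", "PG", "AS"),
                          include_sigma = FALSE) {
  hr_model <- match.arg(hr_model)
  stopifnot(inherits(record, "species_record"))
  T <- cond$T
  comp <- .lnq_components(record, cond, hr_model, include_sigma)
  R <- .pc$R_kcal
  E_elec <- record$energy * .pc$hartree_kcalmol
  U <- R * T^2 * comp$dlnQ + E_elec
  H <- U + R * T
  S <- .pc$R_cal * (comp$lnQ + T * comp$dlnQ + 1)
  G <- H - T * S / 1000
  real_nu <- record$frequencies[record$frequencies > 0]
  ZPE <- sum(.pc$wavenumber_J * real_nu / 2) * .pc$N_A / (.pc$cal_J * 1000)
  structure(list(T = T, P = cond$P, ZPE = ZPE, U = U, H = H, S = S, G = G,
                 lnQ = comp$lnQ, dlnQ_dT = comp$dlnQ, components = comp,
                 hr_model = hr_model,
                 standard_state = sprintf("%g atm", cond$P)),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %.2f K, %s\n", x$T, x$standard_state))
  cat(sprintf("  ZPE = %.4f kcal/mol\n", x$ZPE))
  cat(sprintf("  U = %.6f  H = %.6f  G = %.6f kcal/mol\n", x$U, x$H, x$G))
  cat(sprintf("  S = %.4f cal/mol/K\n", x$S))
  invisible(x)
}

#' Generalized Gibbs activation energy with standard-state bookkeeping
#'
#' Computes the activation Gibbs energy from reactant and
#' generalized-transition-state records at 1 atm,
#' `dG(1 atm) = G_GTS - sum_i G_Ri` (electronic energies included in G),
#' and converts it to the 1 M standard state through the relation between
#' pressure- and concentration-based equilibrium constants:
#' `dG(1M) = dG(1 atm) + dn * RT * ln(V_m * c0)` with `dn = 0` for
#' unimolecular and `dn = -1` for bimolecular reactions.  For a bimolecular
#' reaction at 298.15 K and 1 atm the shift is `-RT ln(24.465) = -1.894`
#' kcal/mol.
#'
#' @param reactants List of 1 or 2 [species_record()]s.
#' @param gts The transition-state or GTS [species_record()].
#' @param cond A [thermo_conditions()] object.
#' @param hr_model Torsion model passed to [thermo_from_Q()].
#' @return List of class `activation_thermo` with `dG_1atm`, `dG_1M`
#'   (kcal/mol), `dn`, `T`, `V_m` and the per-species `thermo_state`s.
#' @export
activation_thermo <- function(reactants, gts, cond = thermo_conditions(),
                              hr_model = "HO") {
  if (inherits(reactants, "species_record")) reactants <- list(reactants)
  n <- length(reactants)
  if (n < 1L || n > 2L)
    stop("unsupported molecularity: ", n, " reactants (1 or 2 supported)")
  mass_r <- sum(vapply(reactants, function(r) sum(r$atoms$mass), numeric(1)))
  if (abs(mass_r - sum(gts$atoms$mass)) > 1e-6)
    warning("reactant and transition-state masses do not balance")
  th_r <- lapply(reactants, thermo_from_Q, cond = cond, hr_model = hr_model)
  th_g <- thermo_from_Q(gts, cond = cond, hr_model = hr_model)
  dG_1atm <- th_g$G - sum(vapply(th_r, `[[`, numeric(1), "G"))
  dn <- -(n - 1L)
  T <- cond$T
  dG_1M <- dG_1atm +
    dn * .pc$R_kcal * T * log(cond$V_m * .pc$c_standard_M)
  structure(list(dG_1atm = dG_1atm, dG_1M = dG_1M, dn = dn, T = T,
                 V_m = cond$V_m, gts = th_g, reactants = th_r),
            class = "activation_thermo")
}

#' @export
print.activation_thermo <- function(x, ...) {
  cat(sprintf("<activation_thermo> T = %.2f K, dn = %d\n", x$T, x$dn))
  cat(sprintf("  dG(1 atm) = %.4f kcal/mol\n", x$dG_1atm))
  cat(sprintf("  dG(1 M)   = %.4f kcal/mol\n", x$dG_1M))
  invisible(x)
}
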