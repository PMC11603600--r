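# One-dimensional hindered internal rotation.
#
# A torsion is modeled by the periodic potential V(phi) = V0/2 (1 - cos M phi)
# with reduced moment of inertia I_r.  Partition functions:
#   q_FR    free (classical, unhindered) rotor
#   q_CHO   classical harmonic oscillator at the torsional frequency
#   q_HO    quantum harmonic oscillator (bottom-of-well referenced)
#   q_class classical hindered rotor: q_FR * exp(-y/2) * I0(y/2), y = V0/RT
#   q_PG    Pitzer-Gwinn: q_class * q_HO / q_CHO
#   q_AS    q_PG times a rational polynomial correction in x = 1/q_FR and y,
#           in the functional style of Ayala and Schlegel
# An exact Fourier-basis eigensolver of the torsional Schroedinger equation
# serves as the validation oracle.

#' Torsion specification
#'
#' Parameters of one internal rotation: torsional frequency, reduced moment
#' of inertia, number of potential minima over 0..2*pi, torsional symmetry
#' number, and optionally the barrier height.  When `V0` is omitted it is
#' computed from the harmonic relation of the cosine well (see
#' [barrier_from_frequency()]).  If a barrier is supplied (e.g. from a
#' relaxed torsional scan) it takes precedence; a warning is issued when it
#' disagrees with the frequency-derived value by more than a factor of 2.
#'
#' @param nu_tau Torsional frequency in cm^-1 (> 0).
#' @param I_r Reduced moment of inertia in amu Angstrom^2 (> 0).
#' @param M Number of minima along the torsional coordinate (integer >= 1);
#'   defaults to `sigma_tau`.
#' @param sigma_tau Torsional symmetry number (integer >= 1); defaults to
#'   `M`.
#' @param V0 Torsional barrier in kcal/mol, or `NULL` to derive it from
#'   `nu_tau`.
#' @param mode_index Index (into a species record's frequency list) of the
#'   harmonic mode this torsion replaces.
#' @return Object of class `torsion_spec`.
#' @export
torsion_spec <- function(nu_tau, I_r, M = NULL, sigma_tau = NULL, V0 = NULL,
                         mode_index = NULL) {
  if (is.null(M) && is.null(sigma_tau))
    stop("give at least one of `M` and `sigma_tau`")
  if (is.null(M)) M <- sigma_tau
  if (is.null(sigma_tau)) sigma_tau <- M
  M <- as.integer(M); sigma_tau <- as.integer(sigma_tau)
  stopifnot(is.numeric(nu_tau), nu_tau > 0, is.numeric(I_r), I_r > 0,
            M >= 1L, sigma_tau >= 1L)
  spec <- structure(
    list(nu_tau = nu_tau, I_r = I_r, M = M, sigma_tau = sigma_tau,
         V0 = V0, mode_index = if (is.null(mode_index)) NULL
              else as.integer(mode_index)),
    class = "torsion_spec")
  if (!is.null(V0)) {
    v_freq <- barrier_from_frequency(spec)
    ratio <- V0 / v_freq
    if (ratio > 2 || ratio < 0.5)
      warning(sprintf(paste0(
        "supplied barrier V0 = %.3f kcal/mol differs from the ",
        "frequency-derived value %.3f kcal/mol by more than 2x"), V0, v_freq))
  }
  spec
}

#' @export
print.torsion_spec <- function(x, ...) {
  cat(sprintf(
    "<torsion_spec> nu = %.1f cm-1, I_r = %.3f amu A^2, M = %d, sigma = %d\n",
    x$nu_tau, x$I_r, x$M, x$sigma_tau))
  cat(sprintf("  V0 = %.4f kcal/mol (%s)\n", .resolve_V0(x),
              if (is.null(x$V0)) "from frequency" else "supplied"))
  invisible(x)
}

#' Torsional barrier from the harmonic relation
#'
#' For the well `V0/2 (1 - cos(M phi))`, the curvature at a minimum fixes
#' the harmonic torsional frequency, giving
#' `V0 = 8 pi^2 c^2 nu_tau^2 I_r / M^2` per molecule (times the Avogadro
#' constant per mole).
#'
#' @param spec A [torsion_spec()].
#' @return Barrier height in kcal/mol.
#' @export
barrier_from_frequency <- function(spec) {
  if (spec$M < 1L) stop("M must be >= 1")
  I_kg <- spec$I_r * .pc$amu_kg * .pc$angstrom_m^2
  V0_J <- 8 * pi^2 * (.pc$c_cm * spec$nu_tau)^2 * I_kg / spec$M^2
  V0_J * .pc$N_A / (.pc$cal_J * 1000)
}

.resolve_V0 <- function(spec) spec$V0 %||% barrier_from_frequency(spec)

#' Free-rotor partition function
#'
#' `sqrt(8 pi^3 I_r kB T) / (sigma_tau h)`: the classical partition
#' function of an unhindered one-dimensional internal rotation.
#'
#' @param spec A [torsion_spec()].
#' @param T Temperature in K.
#' @return Dimensionless partition function.
#' @export
q_free_rotor <- function(spec, T) {
  I_kg <- spec$I_r * .pc$amu_kg * .pc$angstrom_m^2
  sqrt(8 * pi^3 * I_kg * .pc$kB * T) / (spec$sigma_tau * .pc$h)
}

# Shared dimensionless variables for one torsion at temperature T.
.hr_vars <- function(spec, T) {
  V0 <- .resolve_V0(spec)
  y <- V0 / (.pc$R_kcal * T)
  qfr <- q_free_rotor(spec, T)
  u <- .pc$wavenumber_J * spec$nu_tau / (.pc$kB * T)
  list(V0 = V0, y = y, q_FR = qfr, x = 1 / qfr, u = u)
}

# ln q and d ln q / dT of the Pitzer-Gwinn partition function; all terms
# evaluated with exponentially scaled Bessel functions so that large y
# (deep wells, low T) cannot overflow.
.lnq_pg <- function(spec, T) {
  v <- .hr_vars(spec, T)
  z <- v$y / 2
  r <- besselI(z, 1, expon.scaled = TRUE) / besselI(z, 0, expon.scaled = TRUE)
  ln_class <- log(v$q_FR) + log(besselI(z, 0, expon.scaled = TRUE))
  ln_ho <- -v$u / 2 - log(1 - exp(-v$u))
  lnq <- ln_class + ln_ho + log(v$u)          # + log u  ==  - log q_CHO
  dlnq <- 1 / (2 * T) +
    (v$y / (2 * T)) * (1 - r) +
    (v$u / T) * (0.5 + 1 / expm1(v$u)) -
    1 / T
  list(lnq = lnq, dlnq = dlnq, vars = v, bessel_ratio = r)
}

.hr_result <- function(spec, T, pg, as_corr = NULL) {
  v <- pg$vars
  out <- list(T = T, V0 = v$V0, x = v$x, y = v$y, u = v$u,
              q_FR = v$q_FR,
              q_CHO = 1 / v$u,
              q_HO = exp(-v$u / 2) / (1 - exp(-v$u)),
              q_class = exp(log(v$q_FR) +
                            log(besselI(v$y / 2, 0, expon.scaled = TRUE))),
              q_PG = exp(pg$lnq))
  if (!is.null(as_corr)) {
    out$as_correction <- as_corr
    out$q_AS <- out$q_PG * as_corr
  }
  structure(out, class = "hr_result")
}

#' @export
print.hr_result <- function(x, ...) {
  cat(sprintf("<hr_result> T = %.2f K, V0 = %.4f kcal/mol (y = %.3f)\n",
              x$T, x$V0, x$y))
  cat(sprintf("  q_FR = %.4f  q_HO = %.4f  q_class = %.4f  q_PG = %.4f\n",
              x$q_FR, x$q_HO, x$q_class, x$q_PG))
  if (!is.null(x$q_AS)) cat(sprintf("  q_AS = %.4f\n", x$q_AS))
  invisible(x)
}

#' Pitzer-Gwinn hindered-rotor partition function
#'
#' `q_PG = q_class * q_HO / q_CHO` with
#' `q_class = q_FR exp(-y/2) I0(y/2)`, `y = V0/RT`; `q_HO` is
#' bottom-of-well referenced at the torsional frequency and
#' `q_CHO = kB T/(h c nu_tau)`.  Evaluated with exponentially scaled Bessel
#' functions, so arbitrarily large `y` is safe.
#'
#' @param spec A [torsion_spec()].
#' @param T Temperature in K.
#' @return An `hr_result` with all component partition functions.
#' @export
q_pitzer_gwinn <- function(spec, T) {
  .hr_result(spec, T, .lnq_pg(spec, T))
}

# --- polynomial machinery for the AS-style correction -----------------------

.poly_eval <- function(C, x, y) {
  nx <- nrow(C); ny <- ncol(C)
  xp <- x^(0:(nx - 1)); yp <- y^(0:(ny - 1))
  as.numeric(xp %*% C %*% yp)
}

.poly_eval_dx <- function(C, x, y) {
  nx <- nrow(C)
  if (nx < 2) return(0)
  D <- C[-1, , drop = FALSE] * (1:(nx - 1))
  .poly_eval(D, x, y)
}

.poly_eval_dy <- function(C, x, y) {
  ny <- ncol(C)
  if (ny < 2) return(0)
  D <- C[, -1, drop = FALSE]
  D <- sweep(D, 2, 1:(ny - 1), `*`)
  .poly_eval(D, x, y)
}

# correction c(x,y) = (1 + P2 e^{-y/2}) / (1 + P1 e^{-y/2}) and the partial
# derivatives of ln c needed for the thermodynamic closed forms.
.as_correction <- function(x, y, deriv = FALSE) {
  dom <- .as_domain
  xc <- min(max(x, dom$x[1]), dom$x[2])
  yc <- min(max(y, dom$y[1]), dom$y[2])
  if ((xc != x || yc != y) && (x > dom$x[2] * 1.05 || y > dom$y[2] * 1.05))
    warning(sprintf(
      "(x = %.3f, y = %.3f) outside the fitted correction domain; clamped",
      x, y))
  e <- exp(-yc / 2)
  P1 <- .poly_eval(.as_P1, xc, yc); P2 <- .poly_eval(.as_P2, xc, yc)
  c_val <- (1 + P2 * e) / (1 + P1 * e)
  if (!deriv) return(c_val)
  dlnc_dx <- .poly_eval_dx(.as_P2, xc, yc) * e / (1 + P2 * e) -
             .poly_eval_dx(.as_P1, xc, yc) * e / (1 + P1 * e)
  dlnc_dy <- (.poly_eval_dy(.as_P2, xc, yc) - P2 / 2) * e / (1 + P2 * e) -
             (.poly_eval_dy(.as_P1, xc, yc) - P1 / 2) * e / (1 + P1 * e)
  # outside the clamped box the correction is held constant, so its
  # derivative is zero there
  if (xc != x) dlnc_dx <- 0
  if (yc != y) dlnc_dy <- 0
  list(value = c_val, dlnc_dx = dlnc_dx, dlnc_dy = dlnc_dy)
}

.lnq_as <- function(spec, T) {
  pg <- .lnq_pg(spec, T)
  v <- pg$vars
  corr <- .as_correction(v$x, v$y, deriv = TRUE)
  lnq <- pg$lnq + log(corr$value)
  # x ~ T^{-1/2}, y ~ T^{-1}:  dx/dT = -x/2T, dy/dT = -y/T
  dlnq <- pg$dlnq + corr$dlnc_dx * (-v$x / (2 * T)) +
    corr$dlnc_dy * (-v$y / T)
  list(lnq = lnq, dlnq = dlnq, vars = v, pg = pg, correction = corr$value)
}

#' Ayala-Schlegel-style hindered-rotor partition function
#'
#' Multiplies the Pitzer-Gwinn value by a rational correction
#' `(1 + P2(x, y) exp(-y/2)) / (1 + P1(x, y) exp(-y/2))` where `P1` and
#' `P2` are fifth-order polynomials in `x = 1/q_FR` and `y = V0/RT` with no
#' constant term, so the correction tends to 1 in the free-rotor limit.
#' The polynomial coefficients shipped with the package were calibrated
#' against the exact torsional eigensolver ([torsion_oracle()]) over the
#' domain `x` in (0, 0.6], `y` in [0, 12]; outside that domain the
#' evaluation is clamped with a warning.
#'
#' @param spec A [torsion_spec()].
#' @param T Temperature in K.
#' @return An `hr_result` including `q_AS` and the correction factor.
#' @export
q_ayala_schlegel <- function(spec, T) {
  pg <- .lnq_pg(spec, T)
  corr <- .as_correction(pg$vars$x, pg$vars$y)
  .hr_result(spec, T, pg, as_corr = corr)
}

# Property rows from (ln q, d ln q/dT): per-mode contributions, so H = U and
# G = -RT ln q = H - T S.
.hr_props <- function(lnq, dlnq, T) {
  R <- .pc$R_kcal
  U <- R * T^2 * dlnq
  S <- 1000 * (R * lnq + U / T)          # cal/mol/K
  c(q = exp(lnq), U = U, S = S, H = U, G = -R * T * lnq)
}

#' Pitzer-Gwinn hindered-rotor thermodynamic properties
#'
#' Assembles the per-mole internal energy, entropy, enthalpy and Gibbs
#' energy contributions of one hindered rotor under the Pitzer-Gwinn model,
#' row by row: free rotor, classical harmonic oscillator, quantum harmonic
#' oscillator, classical hindered rotor (whose closed forms carry the
#' modified Bessel functions `I0` and `I1` of `y/2`), and the total
#' `PG = classical + quantum HO - classical HO`.  Each row satisfies
#' `G = H - T S` exactly, and the totals equal `RT^2 d ln q_PG/dT` etc. by
#' construction.
#'
#' @param spec A [torsion_spec()].
#' @param T Temperature in K.
#' @return Object of class `hr_thermo`: a data frame `table` with columns
#'   `row`, `q`, `U`, `H`, `G` (kcal/mol) and `S` (cal/mol/K), plus the
#'   dimensionless variables.
#' @export
hr_thermo_pg <- function(spec, T) {
  pg <- .lnq_pg(spec, T)
  v <- pg$vars
  z <- v$y / 2
  ln_fr <- log(v$q_FR)
  ln_cho <- -log(v$u)
  ln_qho <- -v$u / 2 - log(1 - exp(-v$u))
  ln_cl <- ln_fr + log(besselI(z, 0, expon.scaled = TRUE))
  rows <- rbind(
    free_rotor = .hr_props(ln_fr, 1 / (2 * T), T),
    classical_HO = .hr_props(ln_cho, 1 / T, T),
    quantum_HO = .hr_props(ln_qho, (v$u / T) * (0.5 + 1 / expm1(v$u)), T),
    classical = .hr_props(ln_cl,
                          1 / (2 * T) + (v$y / (2 * T)) * (1 - pg$bessel_ratio),
                          T),
    total = .hr_props(pg$lnq, pg$dlnq, T))
  tab <- data.frame(row = rownames(rows), rows, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(model = "PG", T = T, V0 = v$V0, x = v$x, y = v$y, u = v$u,
                 table = tab), class = "hr_thermo")
}

#' Ayala-Schlegel-style hindered-rotor thermodynamic properties
#'
#' Closed-form per-mole properties of one hindered rotor under the
#' polynomial-corrected model: the temperature derivative of the correction
#' factor is evaluated analytically from the polynomial partials together
#' with `dx/dT = -x/2T` and `dy/dT = -y/T`, and added to the Pitzer-Gwinn
#' closed forms.  The result agrees with numerical differentiation of
#' `ln q_AS` to better than 1e-5 relative (this is asserted in the test
#' suite, where the numerical derivative is the cross-check).
#'
#' @param spec A [torsion_spec()].
#' @param T Temperature in K.
#' @return Object of class `hr_thermo` with rows `total_PG` and `total_AS`.
#' @export
hr_thermo_as <- function(spec, T) {
  as_ <- .lnq_as(spec, T)
  rows <- rbind(
    total_PG = .hr_props(as_$pg$lnq, as_$pg$dlnq, T),
    total_AS = .hr_props(as_$lnq, as_$dlnq, T))
  tab <- data.frame(row = rownames(rows), rows, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(model = "AS", T = T, V0 = as_$vars$V0, x = as_$vars$x,
                 y = as_$vars$y, u = as_$vars$u,
                 correction = as_$correction, table = tab),
            class = "hr_thermo")
}

#' @export
print.hr_thermo <- function(x, ...) {
  cat(sprintf("<hr_thermo %s> T = %.2f K, V0 = %.4f kcal/mol, y = %.3f\n",
              x$model, x$T, x$V0, x$y))
  print(x$table, digits = 6)
  invisible(x)
}

# ln q_vib and d ln q_vib/dT for a species record under a torsion model.
# Harmonic modes contribute the bottom-referenced HO terms; each torsion
# replaces its harmonic mode by the chosen hindered-rotor treatment.
.vib_lnq <- function(record, T, model = c("HO", "PG", "AS")) {
  model <- match.arg(model)
  nu <- record$frequencies
  replaced <- integer()
  tors <- list()
  if (model != "HO" && length(record$torsions)) {
    tors <- record$torsions
    idx <- vapply(tors, function(tor) {
      i <- tor$mode_index
      if (is.null(i)) {
        cand <- which(abs(nu - tor$nu_tau) < 1)
        if (!length(cand))
          stop("no harmonic mode within 1 cm^-1 of the torsional frequency ",
               tor$nu_tau, "; give `mode_index` explicitly")
        i <- cand[1]
      }
      if (i < 1L || i > length(nu)) stop("torsion mode_index out of range")
      if (nu[i] < 0)
        stop("torsion mode_index points at the imaginary mode")
      as.integer(i)
    }, integer(1))
    if (anyDuplicated(idx)) stop("torsion mode indices must be distinct")
    replaced <- idx
  }
  keep <- setdiff(which(nu > 0), replaced)
  lnq <- 0; dlnq <- 0
  if (length(keep)) {
    u <- .pc$wavenumber_J * nu[keep] / (.pc$kB * T)
    lnq <- sum(-u / 2 - log(1 - exp(-u)))
    dlnq <- sum((u / T) * (0.5 + 1 / expm1(u)))
  }
  for (tor in tors) {
    hr <- if (model == "PG") .lnq_pg(tor, T) else .lnq_as(tor, T)
    lnq <- lnq + hr$lnq
    dlnq <- dlnq + hr$dlnq
  }
  list(lnq = lnq, dlnq = dlnq, n_torsion = length(tors))
}

#' Vibrational partition function with torsion treatment
#'
#' Decomposes the vibrational partition function into nontorsional and
#' torsional contributions: `q_vib = prod_i q_HO(nu_i) * prod_t q_HR(t)`
#' over the `F - t` nontorsional harmonic modes and the `t` independent
#' hindered rotors.  With `model = "HO"` every torsion reverts to its
#' harmonic mode and the result is identical to [q_vibrational_HO()] on
#' the real frequencies.  Imaginary modes (the reaction coordinate of a TS
#' record) are excluded.
#'
#' @param record A [species_record()].
#' @param T Temperature in K.
#' @param model `"HO"`, `"PG"` or `"AS"`.
#' @return Dimensionless vibrational partition function.
#' @export
compose_vibrational <- function(record, T, model = c("HO", "PG", "AS")) {
  model <- match.arg(model)
  exp(.vib_lnq(record, T, model)$lnq)
}

#' Exact torsional partition function by eigensolve
#'
#' Validation oracle: diagonalizes the one-dimensional torsional
#' Hamiltonian `H = -(hbar^2 / 2 I_r) d^2/dphi^2 + V0/2 (1 - cos M phi)`
#' on a periodic Fourier basis of `n_grid` plane waves (a dense symmetric
#' eigensolve; for a pure cosine potential this is identical to the
#' Fourier-grid Hamiltonian on `n_grid` points), Boltzmann-sums the
#' eigenvalues referenced to the potential minimum, and divides by the
#' torsional symmetry number.  This is a validation tool, not a production
#' method.
#'
#' @param spec A [torsion_spec()].
#' @param T Temperature in K.
#' @param n_grid Number of basis functions (>= 512 recommended for
#'   production-accuracy checks; smaller values are refused).
#' @param check_convergence If `TRUE`, re-solve with `2 * n_grid` and error
#'   if the result moves by more than 1e-8 relative.
#' @return Dimensionless partition function.
#' @export
torsion_oracle <- function(spec, T, n_grid = 1024, check_convergence = FALSE) {
  if (n_grid < 64) stop("n_grid too small for a meaningful eigensolve")
  q1 <- .torsion_oracle_once(spec, T, n_grid)
  if (check_convergence) {
    q2 <- .torsion_oracle_once(spec, T, 2L * n_grid)
    if (abs(q2 / q1 - 1) > 1e-8)
      stop(sprintf(
        "torsional eigensolve not converged at n_grid = %d (rel change %.2e)",
        n_grid, abs(q2 / q1 - 1)))
  }
  q1
}

.torsion_oracle_once <- function(spec, T, n_grid) {
  V0 <- .resolve_V0(spec) * .pc$cal_J * 1000 / .pc$N_A   # J per molecule
  I_kg <- spec$I_r * .pc$amu_kg * .pc$angstrom_m^2
  B <- (.pc$h / (2 * pi))^2 / (2 * I_kg)                 # J
  jmax <- (n_grid - 1L) %/% 2L
  j <- (-jmax):jmax
  n <- length(j)
  # <j|H|j'> for V = V0/2 (1 - cos M phi): diagonal B j^2 + V0/2,
  # off-diagonal -V0/4 at |j - j'| = M.  Exact in this basis.
  H <- diag(B * j^2 + V0 / 2)
  M <- spec$M
  if (M < n) {
    off <- seq_len(n - M)
    H[cbind(off, off + M)] <- -V0 / 4
    H[cbind(off + M, off)] <- -V0 / 4
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  kT <- .pc$kB * T
  sum(exp(-(ev - 0) / kT)) / spec$sigma_tau    # potential minimum is 0
}
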