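# Rate constants via the thermodynamic formulation.
#
#   k_GT(s, T) = sigma_Rx * (kB T / h) * (c0)^dn * exp(-dG_GT(1M) / RT)
#
# with sigma-free partition functions inside dG and the reaction symmetry
# applied once through sigma_Rx.  CVT minimizes k_GT over the computed
# generalized-transition-state series (equivalently, maximizes dG_GT);
# tunneling multiplies the classical rate by the Eckart transmission
# coefficient.

#' Assemble a reaction system
#'
#' @param reactants List of 1 or 2 reactant [species_record()]s.
#' @param ts The saddle-point [species_record()] (role `"TS"`, exactly one
#'   imaginary frequency).
#' @param gts_series Optional list of `GTS` records at nonstationary path
#'   points; their `s_value`s must be distinct and nonzero.
#' @param products Optional list of product / complex records (carried for
#'   reporting and for the reverse Eckart barrier; rates are always
#'   computed reactants -> TS).
#' @param sigma_rx_override Optional explicit reaction symmetry factor
#'   (the `RXSYM` mechanism); overrides the record symmetry numbers.
#' @return Object of class `reaction_system`.
#' @export
reaction_system <- function(reactants, ts, gts_series = list(),
                            products = list(), sigma_rx_override = NULL) {
  if (inherits(reactants, "species_record")) reactants <- list(reactants)
  n <- length(reactants)
  if (n < 1L || n > 2L) stop("molecularity must be 1 or 2")
  stopifnot(inherits(ts, "species_record"))
  if (sum(ts$frequencies < 0) != 1L)
    stop("TS record must have exactly one imaginary frequency")
  if (length(gts_series)) {
    sv <- vapply(gts_series, function(g) g$s_value %||% NA_real_, numeric(1))
    if (any(is.na(sv))) stop("every GTS record needs an s_value")
    if (any(sv == 0)) stop("GTS series must exclude s = 0 (that is the TS)")
    if (anyDuplicated(sv)) stop("GTS s_values must be distinct")
    gts_series <- gts_series[order(sv)]
  }
  structure(list(reactants = reactants, ts = ts, gts_series = gts_series,
                 products = products, molecularity = n,
                 sigma_rx_override = sigma_rx_override),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("<reaction_system> %s, %d GTS point(s)\n",
              if (x$molecularity == 1) "unimolecular" else "bimolecular",
              length(x$gts_series)))
  invisible(x)
}

#' Reaction symmetry factor
#'
#' `sigma_Rx = prod(sigma_i^R) / sigma_TS`, constant along the path (the
#' symmetry number of a generalized TS is taken to be that of the saddle
#' point).  An explicit override (`RXSYM`) wins when present.
#'
#' @param system A [reaction_system()].
#' @return The (possibly fractional) symmetry factor.
#' @export
symmetry_factor <- function(system) {
  if (!is.null(system$sigma_rx_override))
    return(as.numeric(system$sigma_rx_override))
  if (system$ts$sigma == 0) stop("sigma_TS must be nonzero")
  prod(vapply(system$reactants, `[[`, integer(1), "sigma")) / system$ts$sigma
}

# rate constant from an activation_thermo object
.k_from_act <- function(act, sigma_rx, molecularity) {
  T <- act$T
  k <- sigma_rx * (.pc$kB * T / .pc$h) *
    exp(-act$dG_1M / (.pc$R_kcal * T))
  if (molecularity == 2L) {
    # (c0)^dn with dn = -1 gives L mol^-1 s^-1; convert to cm^3/molecule/s
    k <- k * 1000 / .pc$N_A
    attr(k, "units") <- "cm^3 molecule^-1 s^-1"
  } else {
    attr(k, "units") <- "s^-1"
  }
  k
}

#' Conventional TST rate constant
#'
#' Thermodynamic-formulation TST with the dividing surface at the saddle
#' point: `k = sigma_Rx (kB T/h) (c0)^dn exp(-dG(1M)/RT)`.  Bimolecular
#' rate constants are returned in cm^3 molecule^-1 s^-1, unimolecular in
#' s^-1.
#'
#' @param system A [reaction_system()].
#' @param T Temperature in K.
#' @param hr_model Torsion treatment inside the partition functions:
#'   `"HO"`, `"PG"` or `"AS"`.
#' @param P Pressure in atm (enters only through the 1 atm -> 1 M
#'   conversion; the result at fixed T is standard-state invariant for
#'   unimolecular reactions).
#' @return Rate constant with a `units` attribute and the activation
#'   thermodynamics attached as attribute `activation`.
#' @export
k_tst <- function(system, T = 298.15, hr_model = "HO", P = 1) {
  cond <- thermo_conditions(T, P)
  act <- activation_thermo(system$reactants, system$ts, cond, hr_model)
  k <- .k_from_act(act, symmetry_factor(system), system$molecularity)
  attr(k, "activation") <- act
  k
}

#' Generalized-TST rate constant at a path point
#'
#' Same form as [k_tst()] with the generalized transition state at
#' reaction coordinate `s` replacing the saddle point.
#'
#' @param system A [reaction_system()].
#' @param s Reaction coordinate of a record in the system's GTS series
#'   (or 0 for the saddle point).
#' @param T Temperature in K.
#' @param hr_model Torsion model.
#' @param P Pressure in atm.
#' @return Rate constant with attributes as in [k_tst()].
#' @export
k_gt <- function(system, s, T = 298.15, hr_model = "HO", P = 1) {
  if (s == 0) return(k_tst(system, T, hr_model, P))
  sv <- vapply(system$gts_series, `[[`, numeric(1), "s_value")
  i <- match(s, sv)
  if (is.na(i)) stop("no GTS record at s = ", s)
  cond <- thermo_conditions(T, P)
  act <- activation_thermo(system$reactants, system$gts_series[[i]], cond,
                           hr_model)
  k <- .k_from_act(act, symmetry_factor(system), system$molecularity)
  attr(k, "activation") <- act
  k
}

#' CVT rate constant
#'
#' Discrete minimum of the generalized rate constant over the candidate
#' set (the computed GTS series plus the saddle point), reported together
#' with the minimizing coordinate `s_cvt_star`.  Minimizing `k_GT` is
#' equivalent to maximizing the generalized Gibbs activation energy.  Ties
#' are broken toward the point closest to `s = 0`, and between equidistant
#' points toward the reactant side.  The reported `s` is always an actual
#' computed point; no interpolation is attempted.
#'
#' @param system A [reaction_system()] with a nonempty GTS series (an
#'   empty series degenerates to TST).
#' @param T Temperature in K.
#' @param hr_model Torsion model.
#' @param P Pressure in atm.
#' @return List with `k` (the CVT rate constant), `s_star`, `k_tst`, and
#'   the full `(s, k, dG_1M)` curve.
#' @export
k_cvt <- function(system, T = 298.15, hr_model = "HO", P = 1) {
  sv <- c(0, vapply(system$gts_series, `[[`, numeric(1), "s_value"))
  ks <- lapply(sv, function(s) k_gt(system, s, T, hr_model, P))
  kv <- vapply(ks, as.numeric, numeric(1))
  dG <- vapply(ks, function(k) attr(k, "activation")$dG_1M, numeric(1))
  o <- order(kv, abs(sv), sv)      # min k, then |s|, then reactant side
  i <- o[1]
  list(k = ks[[i]], s_star = sv[i], k_tst = ks[[1]],
       curve = data.frame(s = sv, k = kv, dG_1M = dG)[order(sv), ])
}

#' ZPE-corrected Eckart barrier from a reaction system
#'
#' Forward barrier: `(E + ZPE)_TS - sum (E + ZPE)_reactants`; reverse
#' barrier likewise against the products (which must be present).  The
#' imaginary frequency magnitude is taken from the saddle point.
#'
#' @param system A [reaction_system()] with products.
#' @return Object of class `eckart_barrier`: `dV1`, `dV2` (kcal/mol) and
#'   `nu_imag` (cm^-1, magnitude).
#' @export
eckart_barrier <- function(system) {
  if (!length(system$products))
    stop("reverse Eckart barrier needs product records")
  zpe <- function(rec) {
    nu <- rec$frequencies[rec$frequencies > 0]
    sum(.pc$wavenumber_J * nu / 2) * .pc$N_A / (.pc$cal_J * 1000)
  }
  e0 <- function(rec) rec$energy * .pc$hartree_kcalmol + zpe(rec)
  eR <- sum(vapply(system$reactants, e0, numeric(1)))
  eP <- sum(vapply(system$products, e0, numeric(1)))
  eTS <- e0(system$ts)
  nu_imag <- abs(min(system$ts$frequencies))
  dV1 <- eTS - eR; dV2 <- eTS - eP
  if (dV1 <= 0 || dV2 <= 0)
    stop("Eckart barriers must be positive (dV1 = ", round(dV1, 3),
         ", dV2 = ", round(dV2, 3), " kcal/mol)")
  structure(list(dV1 = dV1, dV2 = dV2, nu_imag = nu_imag),
            class = "eckart_barrier")
}

#' Eckart tunneling transmission coefficient
#'
#' Boltzmann average of the transmission probability through the
#' asymmetric one-dimensional Eckart barrier fitted to the ZPE-corrected
#' forward and reverse barriers and the saddle-point imaginary frequency.
#' With `alpha_i = 2 pi dV_i / (h nu*)` and `xi = E / dV1`, the
#' transmission probability is
#' `p(E) = (cosh(a+b) - cosh(a-b)) / (cosh(a+b) + cosh(d))` where
#' `a = 2 sqrt(alpha1 xi) / (1/sqrt(alpha1) + 1/sqrt(alpha2))`,
#' `b = 2 sqrt((xi - 1) alpha1 + alpha2) / (1/sqrt(alpha1) + 1/sqrt(alpha2))`,
#' `d = 2 sqrt(alpha1 alpha2 - pi^2/4)` (evaluated as `cos` when the
#' argument is negative), and
#' `kappa = exp(dV1/kT) * integral p(E) exp(-E/kT) dE / kT` from the
#' higher asymptote up to `dV1 + 40 kT` by adaptive quadrature (relative
#' tolerance 1e-8).  `kappa -> 1` as the imaginary frequency tends to 0
#' and decreases monotonically with temperature.
#'
#' @param barrier An [eckart_barrier()] (or list with `dV1`, `dV2` in
#'   kcal/mol and `nu_imag` in cm^-1).
#' @param T Temperature in K.
#' @return Dimensionless transmission coefficient (>= 1 for real
#'   barriers).
#' @export
eckart_kappa <- function(barrier, T) {
  stopifnot(barrier$dV1 > 0, barrier$dV2 > 0, barrier$nu_imag > 0)
  kT <- .pc$kB * T
  to_J <- .pc$cal_J * 1000 / .pc$N_A
  V1 <- barrier$dV1 * to_J; V2 <- barrier$dV2 * to_J
  hnu <- .pc$h * .pc$c_cm * barrier$nu_imag
  a1 <- 2 * pi * V1 / hnu; a2 <- 2 * pi * V2 / hnu
  denom <- 1 / sqrt(a1) + 1 / sqrt(a2)
  d2 <- a1 * a2 - pi^2 / 4
  D <- if (d2 >= 0) 2 * sqrt(d2) else NA_real_
  cosD <- if (d2 < 0) cos(2 * sqrt(-d2)) else NA_real_

  p_of_E <- function(E) {             # E in J, vectorized
    xi <- E / V1
    A <- 2 * sqrt(a1 * xi) / denom
    B <- 2 * sqrt(pmax((xi - 1) * a1 + a2, 0)) / denom
    m <- pmax(A + B, if (d2 >= 0) D else 0)
    num <- exp(A + B - m) + exp(-(A + B) - m) -
           exp((A - B) - m) - exp(-(A - B) - m)
    den <- exp(A + B - m) + exp(-(A + B) - m) +
      (if (d2 >= 0) exp(D - m) + exp(-D - m) else 2 * cosD * exp(-m))
    pmax(num / den, 0)
  }

  e0 <- max(0, V1 - V2) / kT          # no transmission below the asymptote
  emax <- V1 / kT + 40
  integrand <- function(eps) p_of_E(eps * kT) * exp(V1 / kT - eps)
  res <- stats::integrate(integrand, lower = e0, upper = emax,
                          rel.tol = 1e-8, subdivisions = 1000L)
  if (res$message != "OK")
    stop("Eckart Boltzmann integral did not converge: ", res$message)
  res$value
}

#' Sum of pathway rate constants
#'
#' The overall rate constant of a multi-pathway reaction is the sum of the
#' individual pathway rate constants (all of the same molecularity and
#' units).
#'
#' @param ks Numeric vector or list of rate constants; if they carry
#'   `units` attributes these must agree.
#' @return The summed rate constant.
#' @export
overall_rate <- function(ks) {
  un <- unique(unlist(lapply(ks, attr, "units")))
  if (length(un) > 1) stop("mixed rate-constant units: ",
                           paste(un, collapse = " vs "))
  k <- sum(vapply(ks, as.numeric, numeric(1)))
  if (length(un)) attr(k, "units") <- un
  k
}

#' Branching ratios
#'
#' Percentage contribution of each pathway to the overall rate constant,
#' `Gamma_i = 100 k_i / sum k_j`.
#'
#' @param ks Numeric vector or list of pathway rate constants.
#' @return Numeric vector of percentages summing to 100.
#' @export
branching_ratios <- function(ks) {
  kv <- vapply(ks, as.numeric, numeric(1))
  tot <- sum(kv)
  if (tot <= 0) stop("all pathway rate constants are zero")
  100 * kv / tot
}

#' Recrossing factor
#'
#' `k_TST / k_CVT >= 1`: how much conventional TST overestimates the rate
#' because of trajectories that recross the saddle-point dividing surface.
#'
#' @param k_tst TST rate constant.
#' @param k_cvt CVT rate constant at the same temperature.
#' @return Dimensionless factor.
#' @export
recrossing_factor <- function(k_tst, k_cvt) {
  as.numeric(k_tst) / as.numeric(k_cvt)
}
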