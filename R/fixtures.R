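# Synthetic, analytically characterized reaction fixtures.
#
# Toy reactions with closed-form path energetics (sech^2 or asymmetric
# Eckart V(s)) and smooth analytic mode-frequency trajectories nu_i(s),
# so that reaction-force critical points and the variational-TS location
# have brute-force ground truths and the whole pipeline can be exercised
# with no quantum-chemistry program.  These fixtures make no attempt at
# physically realistic potential-energy surfaces; they exist to plant
# known answers.

#' Specification of a synthetic test reaction
#'
#' @param molecularity 1 or 2.
#' @param barrier Forward barrier height in kcal/mol (0 gives the
#'   degenerate zero-barrier system whose TST rate is exactly `kB T / h`).
#' @param L Path width parameter in amu^1/2 bohr.
#' @param shape `"sech2"` (symmetric `barrier * sech^2(s/L)`) or
#'   `"eckart"` (asymmetric, with reaction energy `dE_rxn`).
#' @param dE_rxn Reaction energy in kcal/mol (used by the Eckart shape;
#'   must be < barrier).
#' @param n_side Number of IRC points on each side of the saddle point.
#' @param step IRC step size in amu^1/2 bohr.
#' @param nu_imag Magnitude of the saddle-point imaginary frequency in
#'   cm^-1.
#' @param entropy_shift Amplitude (cm^-1) of a sigmoidal stiffening of one
#'   transitional mode on the reactant side; positive values move the
#'   Gibbs-energy maximum to `s < 0`, increasingly so at high temperature.
#' @param shift_width Width (amu^1/2 bohr) of the sigmoid.
#' @param gts_window Range of `s` over which GTS records are generated.
#' @param seed Integer seed; fixtures are bit-for-bit reproducible from
#'   `(spec, seed)`.
#' @return Object of class `synthetic_reaction_spec`.
#' @export
synthetic_reaction_spec <- function(molecularity = 2, barrier = 8, L = 0.4,
                                    shape = c("sech2", "eckart"),
                                    dE_rxn = -10, n_side = 100, step = 0.05,
                                    nu_imag = 1500, entropy_shift = 0,
                                    shift_width = 0.25,
                                    gts_window = c(-0.6, 0.6), seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(molecularity %in% c(1, 2), barrier >= 0, L > 0, step > 0,
            n_side >= 3)
  if (shape == "eckart" && dE_rxn >= barrier)
    stop("Eckart shape needs dE_rxn < barrier (no interior maximum otherwise)")
  structure(list(molecularity = as.integer(molecularity), barrier = barrier,
                 L = L, shape = shape, dE_rxn = dE_rxn,
                 n_side = as.integer(n_side), step = step, nu_imag = nu_imag,
                 entropy_shift = entropy_shift, shift_width = shift_width,
                 gts_window = gts_window, seed = as.integer(seed)),
            class = "synthetic_reaction_spec")
}

# analytic path potential, kcal/mol relative to reactants
.fixture_V <- function(spec, s) {
  if (spec$shape == "sech2") {
    spec$barrier / cosh(s / spec$L)^2
  } else {
    A <- spec$dE_rxn
    B <- (sqrt(spec$barrier) + sqrt(spec$barrier - A))^2
    ystar <- (B + A) / (B - A)            # places the maximum at s = 0
    y <- ystar * exp(2 * s / spec$L)
    A * y / (1 + y) + B * y / (1 + y)^2
  }
}

# transitional-mode frequencies along the path; column per mode
.fixture_nu <- function(spec, s) {
  base <- c(220, 410, 680, 1120, 1710)
  out <- outer(rep(1, length(s)), base)
  if (spec$entropy_shift != 0) {
    # stiffen the transitional modes on the reactant side: higher nu ->
    # lower entropy -> higher G at s < 0, shifting the Gibbs maximum off
    # the saddle point, increasingly so at high temperature
    w <- c(1, 0.8, 0.6, 0.4, 0.2)
    sig <- spec$entropy_shift / (1 + exp(s / spec$shift_width))
    out <- out + outer(sig, w)
  }
  out
}

.fixture_reactants <- function(spec) {
  r1 <- species_record(
    label = "R1", role = "R1",
    atoms = data.frame(element = c("O", "H", "H"),
                       mass = c(15.99491, 1.00783, 1.00783),
                       x = c(0, 0, 0.9266),
                       y = c(0, 0.9572, -0.2396),
                       z = c(0, 0, 0)),
    energy = -76.40, frequencies = c(1650, 3660, 3760),
    multiplicity = 1L, sigma = 1L)
  if (spec$molecularity == 1L) return(list(r1))
  r2 <- species_record(
    label = "R2", role = "R2",
    atoms = data.frame(element = c("O", "H"),
                       mass = c(15.99491, 1.00783),
                       x = c(0, 0), y = c(0, 0), z = c(0, 0.9697)),
    energy = -75.73, frequencies = 3738,
    multiplicity = 2L, sigma = 1L, linear = TRUE)
  list(r1, r2)
}

.fixture_super_atoms <- function(reactants, gap = 2.2) {
  at <- reactants[[1]]$atoms
  if (length(reactants) == 2L) {
    a2 <- reactants[[2]]$atoms
    a2$x <- a2$x + gap
    at <- rbind(at, a2)
  }
  at
}

#' Generate a synthetic reaction system with ground truth
#'
#' Builds mutually consistent reactant, saddle-point and GTS records, an
#' IRC table, and a ground-truth object holding the analytic
#' reaction-force critical points and the brute-force Gibbs-activation
#' maximizer on the GTS grid at each requested temperature.  The
#' ground-truth Gibbs evaluation is an independent straight-line
#' reimplementation of the partition-function algebra (it does not call
#' the package's thermochemistry route).
#'
#' @param spec A [synthetic_reaction_spec()].
#' @param T_grid Temperatures at which the ground-truth maximizer is
#'   tabulated.
#' @return List with `system` (a [reaction_system()]), `irc` (data frame
#'   `s`, `V` in kcal/mol, `V_hartree`), `e_reactants` (hartree) and
#'   `ground_truth` (`alpha`, `gamma`, and data frame `s_star` per
#'   temperature).
#' @export
make_reaction <- function(spec, T_grid = 298.15) {
  stopifnot(inherits(spec, "synthetic_reaction_spec"))
  set.seed(spec$seed)
  reactants <- .fixture_reactants(spec)
  e_r <- sum(vapply(reactants, `[[`, numeric(1), "energy"))
  frag_modes <- unlist(lapply(reactants, function(r)
    r$frequencies[r$frequencies > 0]))
  super <- .fixture_super_atoms(reactants)

  s_grid <- seq(-spec$n_side, spec$n_side) * spec$step
  V <- .fixture_V(spec, s_grid)
  if (spec$barrier > 0 && which.max(V) != spec$n_side + 1L)
    stop("shape parameters yield no interior maximum at s = 0")

  mk_point <- function(s, role) {
    nu_trans <- as.numeric(.fixture_nu(spec, s))
    freqs <- c(nu_trans, frag_modes)
    if (role == "TS") freqs <- c(-spec$nu_imag, freqs)
    species_record(
      label = if (role == "TS") "TS" else sprintf("GTS_s%+.3f", s),
      role = role, atoms = super,
      energy = e_r + .fixture_V(spec, s) / .pc$hartree_kcalmol,
      frequencies = freqs,
      multiplicity = if (spec$molecularity == 2L) 2L else 1L,
      sigma = 1L, s_value = if (role == "GTS") s else NULL)
  }

  if (spec$barrier == 0) {
    # degenerate zero-barrier system: the TS is the reactant plus the
    # reaction-coordinate mode, so dG+ = 0 and k_TST = kB T / h exactly
    r1 <- reactants[[1]]
    ts <- species_record(label = "TS", role = "TS", atoms = r1$atoms,
                         energy = r1$energy,
                         frequencies = c(-spec$nu_imag, r1$frequencies),
                         multiplicity = 1L, sigma = r1$sigma)
    system <- reaction_system(reactants[1], ts)
    irc <- data.frame(s = s_grid, V = V, V_hartree = e_r + V / .pc$hartree_kcalmol)
    return(list(spec = spec, system = system, irc = irc, e_reactants = e_r,
                ground_truth = list(alpha = NA_real_, gamma = NA_real_,
                                    s_star = data.frame(T = T_grid,
                                                        s_star = 0))))
  }

  ts <- mk_point(0, "TS")
  in_window <- s_grid >= spec$gts_window[1] & s_grid <= spec$gts_window[2] &
    s_grid != 0
  gts <- lapply(s_grid[in_window], mk_point, role = "GTS")
  prod <- species_record(
    label = "P1", role = "P1", atoms = super,
    energy = e_r + min(spec$dE_rxn, -1) / .pc$hartree_kcalmol,
    frequencies = c(as.numeric(.fixture_nu(spec, max(s_grid))), frag_modes),
    multiplicity = if (spec$molecularity == 2L) 2L else 1L, sigma = 1L)
  system <- reaction_system(reactants, ts, gts_series = gts,
                            products = list(prod))

  gt_alpha_gamma <- .fixture_inflections(spec)
  cand_s <- c(0, s_grid[in_window])
  cand_rec <- c(list(ts), gts)
  s_star <- vapply(T_grid, function(T) {
    dG <- vapply(cand_rec, .gt_deltaG, numeric(1),
                 reactants = reactants, T = T)
    # brute-force maximizer; ties toward s = 0 then the reactant side
    o <- order(-dG, abs(cand_s), cand_s)
    cand_s[o[1]]
  }, numeric(1))

  list(spec = spec, system = system,
       irc = data.frame(s = s_grid, V = V,
                        V_hartree = e_r + V / .pc$hartree_kcalmol),
       e_reactants = e_r,
       ground_truth = list(alpha = gt_alpha_gamma[1],
                           gamma = gt_alpha_gamma[2],
                           s_star = data.frame(T = T_grid, s_star = s_star)))
}

# dense brute-force search for the inflection points of the analytic V(s)
.fixture_inflections <- function(spec) {
  if (spec$shape == "sech2") {
    a <- spec$L * atanh(1 / sqrt(3))
    return(c(-a, a))
  }
  s <- seq(-6 * spec$L, 6 * spec$L, length.out = 200001)
  V <- .fixture_V(spec, s)
  Fv <- -diff(V) / diff(s)
  sm <- (s[-1] + s[-length(s)]) / 2
  c(sm[which.min(Fv)], sm[which.max(Fv)])
}

# Independent ground-truth evaluation of dG_GT(1 atm-free form): straight
# reimplementation of ideal-gas lnQ; the standard-state shift is common to
# all s and irrelevant to the maximizer.
.gt_deltaG <- function(gts, reactants, T) {
  h <- 6.62607015e-34; kB <- 1.380649e-23; NAv <- 6.02214076e23
  c_cm <- 2.99792458e10; amu <- 1.66053906660e-27
  hart_kcal <- 4.3597447222071e-18 * NAv / 4184
  R <- kB * NAv / 4184                      # kcal/mol/K
  lnQ <- function(rec) {
    m <- sum(rec$atoms$mass) * amu
    Vol <- kB * T / 101325
    lt <- 1.5 * log(2 * pi * m * kB * T / h^2) + log(Vol)
    lr <- 0
    if (nrow(rec$atoms) >= 2) {
      a <- rec$atoms; mm <- a$mass
      com <- c(sum(mm * a$x), sum(mm * a$y), sum(mm * a$z)) / sum(mm)
      x <- a$x - com[1]; y <- a$y - com[2]; z <- a$z - com[3]
      Imat <- matrix(c(sum(mm * (y^2 + z^2)), -sum(mm * x * y), -sum(mm * x * z),
                       -sum(mm * x * y), sum(mm * (x^2 + z^2)), -sum(mm * y * z),
                       -sum(mm * x * z), -sum(mm * y * z), sum(mm * (x^2 + y^2))),
                     3, 3) * amu * 1e-20
      ev <- sort(eigen(Imat, symmetric = TRUE, only.values = TRUE)$values)
      fac <- 8 * pi^2 * kB * T / h^2
      lr <- if (isTRUE(rec$linear)) log(fac * ev[3]) else
        0.5 * log(pi) + 0.5 * sum(log(fac * ev))
    }
    nu <- rec$frequencies[rec$frequencies > 0]
    u <- h * c_cm * nu / (kB * T)
    lv <- sum(-u / 2 - log(1 - exp(-u)))
    le <- log(sum(rec$levels[, 1] *
                  exp(-h * c_cm * rec$levels[, 2] / (kB * T))))
    lt + lr + lv + le
  }
  G <- function(rec) rec$energy * hart_kcal - R * T * lnQ(rec)
  G(gts) - sum(vapply(reactants, G, numeric(1)))
}

#' Torsion case with an exact oracle table
#'
#' Builds a [torsion_spec()] whose torsional frequency follows from the
#' requested barrier through the harmonic relation of the cosine well, and
#' tabulates the exact eigensolver partition function over a temperature
#' grid.
#'
#' @param V0 Barrier in kcal/mol.
#' @param I_r Reduced moment of inertia in amu Angstrom^2.
#' @param M Number of minima.
#' @param sigma_tau Torsional symmetry number (defaults to `M`).
#' @param T_grid Temperatures in K.
#' @param n_grid Eigensolver basis size.
#' @return List with `spec` and data frame `oracle` (`T`, `q_exact`).
#' @export
make_torsion_case <- function(V0, I_r, M, sigma_tau = M,
                              T_grid = c(298.15, 500, 1000), n_grid = 1024) {
  stopifnot(V0 >= 0, I_r > 0, M >= 1)
  I_kg <- I_r * .pc$amu_kg * .pc$angstrom_m^2
  V0_J <- V0 * .pc$cal_J * 1000 / .pc$N_A
  nu <- if (V0 > 0) M * sqrt(V0_J / (8 * pi^2 * I_kg)) / .pc$c_cm else 1e-3
  spec <- torsion_spec(nu_tau = nu, I_r = I_r, M = M, sigma_tau = sigma_tau,
                       V0 = if (V0 > 0) V0 else NULL)
  if (V0 == 0) spec$V0 <- 0
  q <- vapply(T_grid, function(T) torsion_oracle(spec, T, n_grid), numeric(1))
  list(spec = spec, oracle = data.frame(T = T_grid, q_exact = q))
}

#' Write a complete on-disk fixture tree
#'
#' Mirrors a real run directory: species records (neutral format or the
#' minimal vendor-log dialect), IRC branch files, a path-points directory
#' with the GTS records, a frequency-job template and a run-control
#' `.eif` file - sufficient for an end-to-end command-line test.
#'
#' @param outdir Output directory (created).
#' @param spec A [synthetic_reaction_spec()].
#' @param format `"record"` for the neutral text schema or `"log"` for the
#'   vendor-log dialect.
#' @param method `"CVT"` or `"TST"` written into the `.eif`.
#' @param temperatures Temperature grid written into the `.eif`.
#' @param eckart Request tunneling in the `.eif`?
#' @return Path of the generated `.eif` file.
#' @export
write_fixture_tree <- function(outdir, spec, format = c("record", "log"),
                               method = if (spec$barrier > 0) "CVT" else "TST",
                               temperatures = 298.15, eckart = FALSE) {
  format <- match.arg(format)
  fx <- make_reaction(spec, T_grid = temperatures)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pp_dir <- file.path(outdir, "pathpoints")
  dir.create(pp_dir, showWarnings = FALSE)

  ext <- if (format == "record") ".rec" else ".log"
  wr <- function(rec, name, dir = outdir) {
    f <- file.path(dir, paste0(name, ext))
    if (format == "record") write_species_record(rec, f) else write_qc_log(rec, f)
    f
  }
  sys <- fx$system
  files <- c(REACT1 = wr(sys$reactants[[1]], "react1"))
  if (sys$molecularity == 2L)
    files["REACT2"] <- wr(sys$reactants[[2]], "react2")
  files["TS"] <- wr(sys$ts, "ts")
  if (length(sys$products)) files["PROD1"] <- wr(sys$products[[1]], "prod1")
  for (g in sys$gts_series) wr(g, sprintf("gts_s%+.3f", g$s_value), pp_dir)

  neg <- fx$irc[fx$irc$s <= 0, ]
  pos <- fx$irc[fx$irc$s >= 0, ]
  irc1 <- file.path(outdir, "irc_reactant.dat")
  irc2 <- file.path(outdir, "irc_product.dat")
  utils::write.table(data.frame(s = neg$s, V = sprintf("%.12f", neg$V_hartree)),
                     irc1, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(s = pos$s, V = sprintf("%.12f", pos$V_hartree)),
                     irc2, row.names = FALSE, col.names = FALSE, quote = FALSE)

  tmpl <- file.path(outdir, "freqjob.tmpl")
  writeLines(c("%chk=pathpoint_{S_VALUE}", "# freq", "", "path point {S_VALUE}",
               "", "0 2", "{GEOMETRY}", ""), tmpl)

  eif <- file.path(outdir, "run.eif")
  lines <- c(
    "# synthetic fixture run-control file",
    paste("METHOD", method),
    paste("REACT1", basename(files["REACT1"])))
  if ("REACT2" %in% names(files))
    lines <- c(lines, paste("REACT2", basename(files["REACT2"])))
  lines <- c(lines, paste("TS", basename(files["TS"])))
  if ("PROD1" %in% names(files))
    lines <- c(lines, paste("PROD1", basename(files["PROD1"])))
  lines <- c(lines,
             paste("IRC", basename(irc1), basename(irc2)),
             "PATHPOINTS pathpoints",
             paste("PATHPOINTS_INP", basename(tmpl)),
             paste("TEMPERATURE", paste(temperatures, collapse = " ")),
             "PRESSURE 1")
  if (eckart) lines <- c(lines, "ECKART TRUE")
  writeLines(lines, eif)
  eif
}
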