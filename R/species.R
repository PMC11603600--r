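# Species records: the unit of thermochemistry.  One record carries the
# geometry, masses, electronic energy, harmonic frequencies, electronic
# levels, rotational symmetry number and (optionally) torsion parameters of
# a single chemical species or generalized-transition-state point.

.species_roles <- c("R1", "R2", "TS", "RC", "PC", "P1", "P2", "GTS")

#' Construct a species record
#'
#' A species record bundles everything statistical thermodynamics needs for
#' one species: Cartesian geometry with per-atom masses, the electronic
#' energy, harmonic frequencies (imaginary modes encoded as negative
#' wavenumbers, the usual quantum-chemistry convention), electronic levels,
#' the rotational symmetry number, and any internal-rotation (torsion)
#' specifications.  A `GTS` record describes a nonstationary point on the
#' minimum-energy path and carries its reaction coordinate `s_value`; its
#' frequencies are expected to come from a reaction-coordinate-projected
#' analysis and must all be real.
#'
#' @param label Free-text species label.
#' @param role One of `"R1"`, `"R2"`, `"TS"`, `"RC"`, `"PC"`, `"P1"`,
#'   `"P2"`, `"GTS"`.
#' @param atoms Data frame with columns `element`, `mass` (amu), `x`, `y`,
#'   `z` (Angstrom).
#' @param energy Electronic energy in hartree.
#' @param frequencies Numeric vector of harmonic wavenumbers in cm^-1;
#'   imaginary modes are negative.  May be empty for a single atom.
#' @param levels Two-column matrix or data frame of electronic levels:
#'   degeneracy and energy above the ground level in cm^-1.  Defaults to a
#'   single level of degeneracy `multiplicity`.
#' @param multiplicity Spin multiplicity used to build the default ground
#'   level when `levels` is not given.
#' @param sigma Rotational symmetry number (positive integer).
#' @param linear Logical; is the species linear?
#' @param charge Integer total charge.
#' @param torsions List of [torsion_spec()] objects (possibly empty).
#' @param s_value Reaction coordinate in amu^1/2 bohr; only meaningful (and
#'   only allowed) for `role = "GTS"`.
#'
#' @return An object of class `species_record`.
#' @seealso [read_species_record()], [write_species_record()]
#' @export
species_record <- function(label, role, atoms, energy, frequencies = numeric(),
                           levels = NULL, multiplicity = 1L, sigma = 1L,
                           linear = FALSE, charge = 0L, torsions = list(),
                           s_value = NULL) {
  role <- match.arg(role, .species_roles)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("element", "mass", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("`atoms` must have columns ", paste(need, collapse = ", "))
  if (nrow(atoms) < 1L) stop("species record needs at least one atom")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("every atomic mass must be positive")
  if (is.null(levels)) levels <- cbind(degeneracy = multiplicity, energy = 0)
  levels <- as.matrix(levels)
  colnames(levels) <- c("degeneracy", "energy")
  if (nrow(levels) < 1L || levels[1, "degeneracy"] < 1 || levels[1, "energy"] != 0)
    stop("need at least one electronic level with degeneracy >= 1 at energy 0")
  sigma <- as.integer(sigma)
  if (is.na(sigma) || sigma < 1L) stop("rotational symmetry number must be >= 1")
  frequencies <- as.numeric(frequencies)
  if (any(!is.finite(frequencies))) stop("non-finite frequency")
  n_imag <- sum(frequencies < 0)
  if (role == "TS" && n_imag != 1L)
    stop("a TS record must have exactly one imaginary frequency, found ", n_imag)
  if (role == "GTS" && n_imag != 0L)
    stop("a GTS record must have no imaginary frequencies after projection, found ",
         n_imag)
  if (!is.null(s_value) && role != "GTS")
    stop("`s_value` is only allowed for role GTS")
  if (is.null(s_value) && role == "GTS")
    stop("a GTS record requires `s_value`")
  if (length(torsions) > 0 &&
      !all(vapply(torsions, inherits, logical(1), "torsion_spec")))
    stop("`torsions` must be a list of torsion_spec objects")
  structure(
    list(label = as.character(label), role = role, atoms = atoms,
         energy = as.numeric(energy), frequencies = frequencies,
         levels = levels, sigma = sigma, linear = isTRUE(linear),
         charge = as.integer(charge), torsions = torsions,
         s_value = if (is.null(s_value)) NULL else as.numeric(s_value)),
    class = "species_record")
}

#' @export
print.species_record <- function(x, ...) {
  cat(sprintf("<species_record> %s (%s)\n", x$label, x$role))
  cat(sprintf("  %d atoms, E = %.8f hartree, sigma = %d%s\n",
              nrow(x$atoms), x$energy, x$sigma,
              if (x$linear) ", linear" else ""))
  if (length(x$frequencies))
    cat(sprintf("  %d frequencies (%d imaginary)\n", length(x$frequencies),
                sum(x$frequencies < 0)))
  if (length(x$torsions))
    cat(sprintf("  %d torsion(s)\n", length(x$torsions)))
  if (!is.null(x$s_value)) cat(sprintf("  s = %g amu^1/2 bohr\n", x$s_value))
  invisible(x)
}

#' Write a species record to the neutral text format
#'
#' The neutral record format is line-oriented plain text: scalar keys
#' (`label`, `role`, `charge`, `sigma`, `linear`, `energy`, `s_value`),
#' one `level` line per electronic level, one `atom` line per atom
#' (element, mass in amu, x/y/z in Angstrom), one `freq` line carrying all
#' wavenumbers, and one `torsion` line per internal rotation with
#' `key=value` fields (`nu`, `I`, `M`, `sigma`, optionally `V0`, `mode`).
#' Blank lines and lines starting with `#` are ignored on input.
#'
#' @param record A [species_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species_record <- function(record, path) {
  stopifnot(inherits(record, "species_record"))
  ln <- c(
    "# vtst species record v1",
    paste("label", record$label),
    paste("role", record$role),
    paste("charge", record$charge),
    paste("sigma", record$sigma),
    paste("linear", record$linear),
    sprintf("energy %.12f", record$energy))
  if (!is.null(record$s_value))
    ln <- c(ln, sprintf("s_value %.6f", record$s_value))
  for (i in seq_len(nrow(record$levels)))
    ln <- c(ln, sprintf("level %d %.6f", as.integer(record$levels[i, 1]),
                        record$levels[i, 2]))
  for (i in seq_len(nrow(record$atoms)))
    ln <- c(ln, sprintf("atom %s %.8f %.10f %.10f %.10f",
                        record$atoms$element[i], record$atoms$mass[i],
                        record$atoms$x[i], record$atoms$y[i], record$atoms$z[i]))
  if (length(record$frequencies))
    ln <- c(ln, paste("freq", paste(sprintf("%.6f", record$frequencies),
                                    collapse = " ")))
  for (tor in record$torsions) {
    fields <- sprintf("nu=%.6f I=%.8f M=%d sigma=%d", tor$nu_tau, tor$I_r,
                      tor$M, tor$sigma_tau)
    if (!is.null(tor$V0)) fields <- paste(fields, sprintf("V0=%.8f", tor$V0))
    if (!is.null(tor$mode_index))
      fields <- paste(fields, sprintf("mode=%d", tor$mode_index))
    ln <- c(ln, paste("torsion", fields))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a species record from the neutral text format
#'
#' Parses the documented record schema (see [write_species_record()]) and
#' validates the result: masses positive, a ground electronic level at zero
#' energy, exactly one imaginary frequency for a `TS` record and none for a
#' `GTS` record.
#'
#' @param path Path to a record file.
#' @return A [species_record()].
#' @export
read_species_record <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("^\\S+", lines))
  val <- trimws(substring(lines, nchar(kv) + 1L))
  get1 <- function(key, mandatory = TRUE) {
    i <- which(kv == key)
    if (!length(i)) {
      if (mandatory) stop("species record schema error: missing field `",
                          key, "` in ", path)
      return(NULL)
    }
    val[i[length(i)]]
  }
  label <- get1("label"); role <- get1("role")
  energy <- as.numeric(get1("energy"))
  if (is.na(energy)) stop("species record schema error: bad `energy` in ", path)
  sigma <- as.integer(get1("sigma", FALSE) %||% "1")
  charge <- as.integer(get1("charge", FALSE) %||% "0")
  linear <- toupper(get1("linear", FALSE) %||% "FALSE") %in% c("TRUE", "T", "YES")
  s_value <- get1("s_value", FALSE)
  if (!is.null(s_value)) s_value <- as.numeric(s_value)

  lv <- which(kv == "level")
  levels <- NULL
  if (length(lv)) {
    parts <- lapply(strsplit(val[lv], "\\s+"), as.numeric)
    levels <- do.call(rbind, parts)
    colnames(levels) <- c("degeneracy", "energy")
  } else {
    mult <- as.integer(get1("multiplicity", FALSE) %||% "1")
    levels <- cbind(degeneracy = mult, energy = 0)
  }

  at <- which(kv == "atom")
  if (!length(at)) stop("species record schema error: missing field `atom` in ", path)
  parts <- strsplit(val[at], "\\s+")
  atoms <- data.frame(
    element = vapply(parts, `[`, character(1), 1L),
    mass = as.numeric(vapply(parts, `[`, character(1), 2L)),
    x = as.numeric(vapply(parts, `[`, character(1), 3L)),
    y = as.numeric(vapply(parts, `[`, character(1), 4L)),
    z = as.numeric(vapply(parts, `[`, character(1), 5L)),
    stringsAsFactors = FALSE)

  fq <- which(kv == "freq")
  frequencies <- if (length(fq))
    as.numeric(unlist(strsplit(val[fq], "\\s+"))) else numeric()

  trs <- which(kv == "torsion")
  torsions <- lapply(val[trs], function(s) {
    fields <- strsplit(strsplit(s, "\\s+")[[1]], "=")
    nm <- vapply(fields, `[`, character(1), 1L)
    vv <- vapply(fields, `[`, character(1), 2L)
    g <- function(k) if (k %in% nm) as.numeric(vv[match(k, nm)]) else NULL
    torsion_spec(nu_tau = g("nu"), I_r = g("I"), M = g("M"),
                 sigma_tau = g("sigma") %||% g("M"), V0 = g("V0"),
                 mode_index = g("mode"))
  })

  species_record(label = label, role = role, atoms = atoms, energy = energy,
                 frequencies = frequencies, levels = levels, sigma = sigma,
                 linear = linear, charge = charge, torsions = torsions,
                 s_value = s_value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
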