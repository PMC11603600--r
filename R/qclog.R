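# Adapter for quantum-chemistry frequency-job log files (the common
# vendor dialect with "Standard orientation", "SCF Done", "Frequencies --"
# and thermochemistry mass lines).  The neutral record format is the
# canonical input; this adapter exists so completed frequency analyses can
# be ingested directly.  The fixture generator writes the same minimal
# dialect, which is what the parser contract is tested against.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr")

#' Parse a quantum-chemistry frequency-job log
#'
#' Extracts the final geometry ("Standard orientation" block), per-atom
#' masses (thermochemistry "has atomic number ... and mass" lines), the
#' final electronic energy ("SCF Done"), harmonic frequencies
#' ("Frequencies --" lines; when several frequency analyses are present
#' the last block wins, with a warning), spin multiplicity, and the
#' rotational symmetry number (default 1 with a warning when absent).
#'
#' @param path Path to the log file.
#' @param role Species role to assign to the parsed record.
#' @param label Label for the record; defaults to the file name.
#' @param s_value Reaction coordinate for `role = "GTS"` records.
#' @return A [species_record()].
#' @export
parse_qc_log <- function(path, role = "R1", label = NULL, s_value = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("Normal termination", lines))) {
    offset <- sum(nchar(lines, type = "bytes") + 1L)
    stop("truncated log (no normal termination) in ", path,
         "; parsed to byte offset ", offset)
  }

  geo_starts <- grep("Standard orientation:", lines)
  if (!length(geo_starts)) stop("no geometry block in ", path)
  g0 <- geo_starts[length(geo_starts)]
  seps <- grep("^ *-{20,}", lines)
  seps <- seps[seps > g0]
  if (length(seps) < 3) stop("malformed geometry block in ", path)
  rows <- lines[(seps[2] + 1L):(seps[3] - 1L)]
  geo <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  z <- geo[, 2]
  coords <- geo[, (ncol(geo) - 2):ncol(geo), drop = FALSE]

  mass_lines <- grep("has atomic number .* and mass", lines, value = TRUE)
  if (length(mass_lines) < nrow(geo))
    stop("no per-atom masses (thermochemistry block missing) in ", path)
  mass_lines <- utils::tail(mass_lines, nrow(geo))
  masses <- as.numeric(sub(".*and mass *", "", mass_lines))

  scf <- grep("SCF Done:", lines, value = TRUE)
  if (!length(scf)) stop("no electronic energy (SCF Done) in ", path)
  energy <- as.numeric(sub(".*= *(-?[0-9.]+).*", "\\1",
                           scf[length(scf)]))

  freq_heads <- grep("Harmonic frequencies", lines)
  freq_line_idx <- grep("Frequencies --", lines)
  if (!length(freq_line_idx))
    stop("no frequency analysis in ", path)
  if (length(freq_heads) > 1) {
    warning("multiple frequency analyses in ", path, "; using the last")
    freq_line_idx <- freq_line_idx[freq_line_idx > freq_heads[length(freq_heads)]]
  }
  freqs <- unlist(lapply(lines[freq_line_idx], function(l)
    as.numeric(strsplit(trimws(sub(".*Frequencies --", "", l)),
                        "\\s+")[[1]])))

  mult_line <- grep("Multiplicity *=", lines, value = TRUE)
  mult <- if (length(mult_line))
    as.integer(sub(".*Multiplicity *= *([0-9]+).*", "\\1", mult_line[1])) else 1L

  sig_line <- grep("Rotational symmetry number", lines, value = TRUE)
  if (length(sig_line)) {
    sigma <- as.integer(sub(".*Rotational symmetry number *([0-9]+).*",
                            "\\1", sig_line[length(sig_line)]))
  } else {
    warning("no rotational symmetry number in ", path, "; defaulting to 1")
    sigma <- 1L
  }

  charge_line <- grep("Charge *=", lines, value = TRUE)
  charge <- if (length(charge_line))
    as.integer(sub(".*Charge *= *(-?[0-9]+).*", "\\1", charge_line[1])) else 0L

  # linearity from the principal moments of the parsed geometry
  elem <- .element_symbols[z]
  elem[is.na(elem)] <- paste0("Z", z[is.na(elem)])
  atoms <- data.frame(element = elem, mass = masses,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  linear <- FALSE
  if (nrow(atoms) >= 2) {
    rec0 <- list(atoms = atoms)
    mom <- principal_moments(structure(rec0, class = "species_record"))
    linear <- mom[1] < 1e-6 * max(mom[3], 1)
  }

  species_record(label = label %||% basename(path), role = role,
                 atoms = atoms, energy = energy, frequencies = freqs,
                 multiplicity = mult, sigma = sigma, linear = linear,
                 charge = charge, s_value = s_value)
}

#' Write a minimal frequency-job log for a species record
#'
#' Emits the minimal vendor-dialect log containing exactly the blocks
#' [parse_qc_log()] reads (geometry, SCF energy, frequencies, masses,
#' multiplicity, symmetry number).  Used by the fixture generator so the
#' adapter can be exercised without any quantum-chemistry program.
#'
#' @param record A [species_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_log <- function(record, path) {
  z <- match(record$atoms$element, .element_symbols)
  z[is.na(z)] <- 1L
  n <- nrow(record$atoms)
  sep <- paste(rep("-", 69), collapse = "")
  geo <- sprintf(" %6d %10d %11d %15.6f %11.6f %11.6f",
                 seq_len(n), z, 0L,
                 record$atoms$x, record$atoms$y, record$atoms$z)
  freq_lines <- character()
  if (length(record$frequencies)) {
    groups <- split(record$frequencies,
                    (seq_along(record$frequencies) - 1L) %/% 3L)
    freq_lines <- c(" Harmonic frequencies (cm**-1):",
                    vapply(groups, function(g)
                      paste0(" Frequencies --",
                             paste(sprintf("%12.4f", g), collapse = " ")),
                      character(1)))
  }
  mass_lines <- sprintf(" Atom %5d has atomic number %3d and mass %10.5f",
                        seq_len(n), z, record$atoms$mass)
  lines <- c(
    " Entering Gaussian System (synthetic fixture log)",
    sprintf(" Charge = %2d Multiplicity = %d", record$charge,
            as.integer(record$levels[1, 1])),
    "                         Standard orientation:",
    paste0(" ", sep),
    " Center     Atomic      Atomic             Coordinates (Angstroms)",
    " Number     Number       Type             X           Y           Z",
    paste0(" ", sep),
    geo,
    paste0(" ", sep),
    sprintf(" SCF Done:  E(SYN) = %18.9f     A.U. after    1 cycles",
            record$energy),
    sprintf(" Rotational symmetry number %2d.", record$sigma),
    freq_lines,
    " - Thermochemistry -",
    mass_lines,
    " Normal termination of Gaussian (synthetic).")
  writeLines(lines, path)
  invisible(path)
}

#' Emit frequency-job inputs for selected path points
#'
#' Writes one frequency-job input file per selected TS-zone point by
#' substituting each point's geometry into a user template.  The template
#' must contain the placeholder token `{GEOMETRY}` (replaced by
#' `element x y z` lines) and may contain `{S_VALUE}`.  Files are named
#' deterministically from the signed reaction coordinate
#' (`pathpoint_s+0.150.inp`).
#'
#' @param selection Numeric vector of selected `s` values (nonempty).
#' @param geometries Named list mapping each formatted `s` value to a
#'   data frame of atoms (as in a [species_record()]), or a single atoms
#'   data frame reused for every point.
#' @param template Template text (single string or character vector of
#'   lines).
#' @param outdir Output directory (created if needed).
#' @return Character vector of the written file paths.
#' @export
emit_pathpoint_inputs <- function(selection, geometries, template, outdir) {
  if (!length(selection)) stop("no TS-zone points selected")
  template <- paste(template, collapse = "\n")
  if (!grepl("{GEOMETRY}", template, fixed = TRUE))
    stop("template lacks the {GEOMETRY} placeholder")
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  single <- is.data.frame(geometries)
  vapply(selection, function(s) {
    tag <- sprintf("%+.3f", s)
    atoms <- if (single) geometries else geometries[[tag]]
    if (is.null(atoms)) stop("no geometry supplied for s = ", tag)
    geo <- paste(sprintf("%-2s %14.8f %14.8f %14.8f",
                         atoms$element, atoms$x, atoms$y, atoms$z),
                 collapse = "\n")
    body <- gsub("{GEOMETRY}", geo, template, fixed = TRUE)
    body <- gsub("{S_VALUE}", tag, body, fixed = TRUE)
    f <- file.path(outdir, sprintf("pathpoint_s%s.inp", tag))
    writeLines(body, f)
    f
  }, character(1))
}
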