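# Reading and writing the external artifacts: neutral species records, the
# vendor-log adapter, IRC tables, the run-control dialect, path-point input
# emission and the rate table.

test_that("species records round-trip through the neutral text format", {
  # low-frequency methyl-like torsion with a scan barrier; the scan value
  # deliberately disagrees with the harmonic relation, which warns
  tor <- suppressWarnings(torsion_spec(nu_tau = 54, I_r = 1.85, M = 3,
                                       V0 = 0.4, mode_index = 2))
  rec <- species_record(
    "TS1", "TS",
    atoms = data.frame(element = c("C", "H"), mass = c(12, 1.00783),
                       x = c(0, 0), y = c(0, 0), z = c(0, 1.09)),
    energy = -40.123456789012, frequencies = c(-1520.3, 54, 3050.5),
    levels = cbind(c(2, 2), c(0, 140)), sigma = 3L, charge = 0L,
    torsions = list(tor))
  f <- withr::local_tempfile(fileext = ".rec")
  write_species_record(rec, f)
  back <- suppressWarnings(read_species_record(f))
  expect_equal(back$energy, rec$energy, tolerance = 1e-12)
  expect_equal(back$frequencies, rec$frequencies)
  expect_equal(back$atoms$mass, rec$atoms$mass)
  expect_equal(back$levels, rec$levels)
  expect_equal(back$sigma, rec$sigma)
  expect_equal(back$torsions[[1]]$V0, 0.4)
  expect_equal(back$torsions[[1]]$mode_index, 2L)
  expect_equal(sum(back$frequencies < 0), 1L)
})

test_that("record validation enforces the schema invariants", {
  atoms <- data.frame(element = "H", mass = 1.00783, x = 0, y = 0, z = 0)
  # minimal single-atom record with a doubly degenerate ground level
  rec <- species_record("H", "R1", atoms, energy = -0.5, multiplicity = 2L)
  expect_length(rec$torsions, 0)
  expect_equal(unname(rec$levels[1, "degeneracy"]), 2)
  # a TS needs exactly one imaginary frequency
  expect_error(species_record("bad", "TS", atoms, 0, frequencies = c(100)),
               "imaginary")
  # GTS records must be projection-clean and carry s
  expect_error(species_record("bad", "GTS", atoms, 0,
                              frequencies = c(-10, 100), s_value = 0.1),
               "GTS")
  expect_error(species_record("bad", "GTS", atoms, 0, frequencies = 100),
               "s_value")
  # missing mandatory field is named in the error
  f <- withr::local_tempfile(fileext = ".rec")
  writeLines(c("label x", "role R1", "energy -1.0"), f)
  expect_error(read_species_record(f), "atom")
})

test_that("the vendor-log adapter inverts the fixture log writer", {
  rec <- diatomic_record()
  f <- withr::local_tempfile(fileext = ".log")
  write_qc_log(rec, f)
  back <- parse_qc_log(f, role = "R1")
  expect_equal(back$energy, rec$energy, tolerance = 1e-9)
  expect_equal(back$frequencies, rec$frequencies, tolerance = 1e-4)
  expect_equal(back$atoms$mass, rec$atoms$mass, tolerance = 1e-5)
  expect_equal(unname(back$levels[1, "degeneracy"]), 2)
  expect_true(back$linear)

  # truncated log -> parse error carrying a byte offset
  lines <- readLines(f)
  writeLines(lines[seq_len(length(lines) - 1L)], f)
  expect_error(parse_qc_log(f), "byte offset")

  # second frequency analysis: last block wins, with a warning
  write_qc_log(rec, f)
  lines <- readLines(f)
  extra <- c(" Harmonic frequencies (cm**-1):",
             " Frequencies --   1111.0000")
  writeLines(append(lines, extra, after = length(lines) - 1L), f)
  expect_warning(back2 <- parse_qc_log(f), "last")
  expect_equal(back2$frequencies, 1111, tolerance = 1e-6)

  # missing symmetry line -> sigma defaults to 1 with a warning
  write_qc_log(rec, f)
  writeLines(grep("Rotational symmetry", readLines(f), value = TRUE,
                  invert = TRUE), f)
  expect_warning(back3 <- parse_qc_log(f), "symmetry")
  expect_equal(back3$sigma, 1L)
})

test_that("the run-control dialect parses its documented keyword set", {
  f <- withr::local_tempfile(fileext = ".eif")
  writeLines(c(
    "METHOD CVT",
    "REACT1 r1.log", "REACT2 r2.log", "TS ts.log",
    "PROD1 p1.log", "PROD2 p2.log",
    "RXSYM 12",
    "IRC ircf.log ircr.log",
    "PATHPOINTS pathpoints",
    "PATHPOINTS_INP freq.tmpl",
    "HINDROT PG",
    "RED_MOM_INERT_TS 1.85", "TORFREQ_TS 54.0", "TORNSYM_TS 3",
    "TEMPERATURE 298.15 300 350",
    "PRESSURE 1"), f)
  expect_no_warning(cfg <- parse_eif(f))
  expect_equal(cfg$method, "CVT")
  expect_equal(cfg$hindrot, "PG")
  expect_equal(cfg$rxsym, 12)
  expect_length(cfg$irc_files, 2)
  expect_equal(cfg$torsion_params$TS$I_r, 1.85)
  expect_equal(cfg$torsion_params$TS$nu_tau, 54)
  expect_equal(cfg$temperatures, c(298.15, 300, 350))

  # unknown keys warn and are reported, never silently dropped
  writeLines(c("METHOD TST", "TS ts.log", "FROBNICATE yes"), f)
  expect_warning(cfg2 <- parse_eif(f), "FROBNICATE")
  expect_true("FROBNICATE" %in% cfg2$unknown)

  writeLines(character(), f)
  expect_error(parse_eif(f), "METHOD")
  writeLines(c("METHOD CVT", "RXSYM twelve"), f)
  expect_error(parse_eif(f), "RXSYM")
})

test_that("IRC branches merge with the TS at s = 0 and reactant re-zeroing", {
  # two branches of 100 points each plus the shared s = 0 row, step 0.05
  s <- seq(0, 5, by = 0.05)
  e0 <- -152.1
  # exoergic left-to-right read: reactant asymptote is the lower endpoint,
  # which is what the branch-direction heuristic keys on
  Vh <- function(s) e0 + 0.02 / cosh(s / 0.8)^2 + 0.01 * tanh(s / 0.8)
  d1 <- withr::local_tempfile(fileext = ".dat")  # reactant side, unsigned s
  d2 <- withr::local_tempfile(fileext = ".dat")
  write.table(data.frame(s = s, V = sprintf("%.12f", Vh(-s))), d1,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(data.frame(s = s, V = sprintf("%.12f", Vh(s))), d2,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  irc <- read_irc(c(d1, d2), e_reactants = Vh(-5))
  expect_equal(nrow(irc$points), 201)
  expect_true(any(irc$points$s == 0))
  expect_false(is.unsorted(irc$points$s, strictly = TRUE))
  # the branch with the lower far end (reactant side) got negative s
  expect_lt(irc$points$V[1], irc$points$V[nrow(irc$points)])
  # fixture round trip: energies relative to reactants, to the precision
  # the branch files carry
  expect_lt(max(abs(irc$points$V -
                    (Vh(irc$points$s) - Vh(-5)) * 627.5094740631)), 1e-8)

  expect_warning(read_irc(d2, e_reactants = e0), "one side")
  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.0 -1.0", "0.2 -1.1", "0.1 -1.2"), bad)
  expect_error(read_irc(bad), "monotone")
})

test_that("path-point input emission substitutes geometry deterministically", {
  tmpl <- c("%freq job", "s = {S_VALUE}", "{GEOMETRY}", "")
  atoms <- data.frame(element = c("O", "H"), mass = c(16, 1),
                      x = c(0, 0), y = c(0, 0), z = c(0, 0.97))
  dir <- withr::local_tempdir()
  files <- emit_pathpoint_inputs(c(-0.1, 0.05, 0.15), atoms, tmpl, dir)
  expect_length(files, 3)
  expect_true(all(file.exists(files)))
  expect_match(basename(files[1]), "-0.100")
  body <- readLines(files[2])
  expect_true(any(grepl("^O ", body)))
  expect_true(any(grepl("\\+0.050", body)))
  expect_error(emit_pathpoint_inputs(numeric(), atoms, tmpl, dir),
               "no TS-zone")
  expect_error(emit_pathpoint_inputs(0.1, atoms, "no placeholder", dir),
               "GEOMETRY")
})

test_that("rate tables round-trip at full precision with unit headers", {
  fx <- make_reaction(synthetic_reaction_spec(barrier = 8, n_side = 20,
                                              seed = 3))
  res <- compute_rates(fx$system, temperatures = c(250, 298.15, 400),
                       method = "CVT")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(res, f)
  back <- read_rate_table(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$k_TST, res$table$k_TST, tolerance = 1e-12)
  expect_equal(back$k_CVT, res$table$k_CVT, tolerance = 1e-12)
  expect_equal(attr(back, "units"), "cm^3 molecule^-1 s^-1")
  expect_true("k_CVT_disp" %in% names(back))

  fx1 <- make_reaction(synthetic_reaction_spec(molecularity = 1, barrier = 0))
  res1 <- compute_rates(fx1$system, temperatures = 298.15)
  write_rate_table(res1, f)
  expect_equal(attr(read_rate_table(f), "units"), "s^-1")
})
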