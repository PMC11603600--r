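# Calibrate the rational polynomial correction of q_ayala_schlegel()
# against the exact torsional eigensolver, and regenerate
# R/as_coefficients.R.  Run from the repository root:
#   Rscript tools/fit-as-coefficients.R
suppressMessages(devtools::load_all("."))

Tref <- 300
h <- 6.62607015e-34; kB <- 1.380649e-23; NAv <- 6.02214076e23
amu <- 1.66053906660e-27; c_cm <- 2.99792458e10

spec_from_xy <- function(x, y, M) {
  qfr <- 1 / x
  I_kg <- (qfr * M * h)^2 / (8 * pi^3 * kB * Tref)
  I_r <- I_kg / (amu * 1e-20)
  V0 <- y * (kB * NAv / 4184) * Tref           # kcal/mol
  V0_J <- V0 * 4184 / NAv
  nu <- if (V0 > 0) M * sqrt(V0_J / (8 * pi^2 * I_kg)) / c_cm else 1e-6
  s <- structure(list(nu_tau = nu, I_r = I_r, M = as.integer(M),
                      sigma_tau = as.integer(M), V0 = V0,
                      mode_index = NULL), class = "torsion_spec")
  if (V0 == 0) s$V0 <- 0
  s
}

xs <- seq(0.04, 0.60, by = 0.02)
ys <- c(seq(0, 2, by = 0.25), seq(2.5, 6, by = 0.5), seq(7, 12, by = 1))
grid <- expand.grid(x = xs, y = ys, M = c(2, 3))

cat("evaluating", nrow(grid), "oracle points...\n")
f <- mapply(function(x, y, M) {
  s <- spec_from_xy(x, y, M)
  qe <- torsion_oracle(s, Tref, n_grid = 512)
  qpg <- q_pitzer_gwinn(s, Tref)$q_PG
  qe / qpg
}, grid$x, grid$y, grid$M)

# basis: x^i y^j, i + j <= 5, no constant term
pows <- subset(expand.grid(i = 0:5, j = 0:5), i + j <= 5 & i + j > 0)
basis <- mapply(function(i, j) grid$x^i * grid$y^j, pows$i, pows$j)
e <- exp(-grid$y / 2)
# (f - 1) = e * (P2 - f * P1)  -> linear LS in the stacked coefficients
X <- cbind(basis * e, -basis * (f * e))
beta <- qr.solve(X, f - 1)
np <- nrow(pows)
C2 <- matrix(0, 6, 6); C1 <- matrix(0, 6, 6)
C2[cbind(pows$i + 1, pows$j + 1)] <- beta[1:np]
C1[cbind(pows$i + 1, pows$j + 1)] <- beta[np + (1:np)]

pred <- (1 + (basis %*% C2[cbind(pows$i + 1, pows$j + 1)]) * e) /
        (1 + (basis %*% C1[cbind(pows$i + 1, pows$j + 1)]) * e)
rel <- pred / f - 1
cat(sprintf("fit residuals: max |rel| = %.4f, rms = %.5f\n",
            max(abs(rel)), sqrt(mean(rel^2))))

fmt <- function(Cm, name) {
  rows <- apply(Cm, 1, function(r)
    paste0("  c(", paste(sprintf("%.15e", r), collapse = ", "), ")"))
  paste0(".", name, " <- matrix(c(\n", paste(rows, collapse = ",\n"),
         "\n), nrow = 6, byrow = TRUE)")
}

out <- c(
"# Coefficients of the fifth-order correction polynomials P1 and P2 used by",
"# q_ayala_schlegel(): entry (i, j) multiplies x^(i-1) * y^(j-1); only terms",
"# with (i-1) + (j-1) <= 5 are populated and the constant term is zero, so",
"# the correction tends to 1 as x, y -> 0.",
"#",
"# Calibrated against the exact torsional eigensolver (torsion_oracle) on",
"# x in [0.04, 0.6], y in [0, 12], M = sigma in {2, 3}; regenerate with",
"# tools/fit-as-coefficients.R.",
"",
fmt(C1, "as_P1"),
"",
fmt(C2, "as_P2"),
"",
".as_domain <- list(x = c(0, 0.6), y = c(0, 12))")
writeLines(out, "R/as_coefficients.R")
cat("wrote R/as_coefficients.R\n")
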