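# Shared helpers: small analytic constructions used across the suite.

# pinned copies of the defining constants for independent closed forms
kB_ <- 1.380649e-23
h_ <- 6.62607015e-34
NA_ <- 6.02214076e23
c_cm_ <- 2.99792458e10
amu_ <- 1.66053906660e-27
Rkcal_ <- kB_ * NA_ / 4184

# a torsion_spec pinned at given (q_FR, y, M) at temperature Tref; the
# torsional frequency follows from the barrier via the harmonic relation,
# so x = 1/q_FR and y fully determine the dimensionless problem
torsion_from_xy <- function(q_FR, y, M, Tref = 298.15) {
  I_kg <- (q_FR * M * h_)^2 / (8 * pi^3 * kB_ * Tref)
  I_r <- I_kg / (amu_ * 1e-20)
  V0 <- y * Rkcal_ * Tref
  nu <- M * sqrt(V0 * 4184 / NA_ / (8 * pi^2 * I_kg)) / c_cm_
  torsion_spec(nu_tau = nu, I_r = I_r, M = M, V0 = V0)
}

# bottom-referenced harmonic-oscillator q for one mode
q_ho <- function(nu, T) {
  u <- h_ * c_cm_ * nu / (kB_ * T)
  exp(-u / 2) / (1 - exp(-u))
}

# minimal single-atom record
atom_record <- function(mass = 39.948, mult = 1L, energy = 0) {
  species_record("atom", "R1",
                 data.frame(element = "Ar", mass = mass, x = 0, y = 0, z = 0),
                 energy = energy, multiplicity = mult)
}

# rigid diatomic with bond length r along z
diatomic_record <- function(m1 = 15.99491, m2 = 1.00783, r = 0.9697,
                            sigma = 1L, freq = 3738, mult = 2L, energy = 0) {
  species_record("diatomic", "R1",
                 data.frame(element = c("X", "Y"), mass = c(m1, m2),
                            x = 0, y = 0, z = c(0, r)),
                 energy = energy, frequencies = freq, sigma = sigma,
                 multiplicity = mult, linear = TRUE)
}
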