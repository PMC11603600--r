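# Hindered-rotor models against closed forms and the exact eigensolver.

test_that("the harmonic barrier relation scales and closes on itself", {
  s0 <- torsion_spec(nu_tau = 60, I_r = 2, M = 3)
  expect_equal(barrier_from_frequency(torsion_spec(120, 2, 3)) /
               barrier_from_frequency(s0), 4, tolerance = 1e-12)
  expect_equal(barrier_from_frequency(torsion_spec(60, 2, 6)) /
               barrier_from_frequency(s0), 0.25, tolerance = 1e-12)
  # curvature of V0/2 (1 - cos M phi) at phi = 0 reproduces nu_tau:
  # omega = sqrt(V0 M^2 / (2 I)) = 2 pi c nu
  V0_J <- barrier_from_frequency(s0) * 4184 / NA_
  I_kg <- 2 * amu_ * 1e-20
  nu_back <- sqrt(V0_J * 9 / (2 * I_kg)) / (2 * pi * c_cm_)
  expect_equal(nu_back, 60, tolerance = 1e-10)
  # supplied scan barrier inconsistent with the frequency by > 2x warns
  expect_warning(torsion_spec(60, 2, 3, V0 = 10 * barrier_from_frequency(s0)),
                 "2x")
})

test_that("the free rotor partition function matches its closed form", {
  s <- torsion_spec(nu_tau = 54, I_r = 1.85, M = 3)
  T <- 298.15
  I_kg <- 1.85 * amu_ * 1e-20
  expect_equal(q_free_rotor(s, T),
               sqrt(8 * pi^3 * I_kg * kB_ * T) / (3 * h_), tolerance = 1e-12)
  expect_equal(q_free_rotor(s, 4 * T) / q_free_rotor(s, T), 2,
               tolerance = 1e-12)
  s6 <- torsion_spec(nu_tau = 54, I_r = 1.85, M = 3, sigma_tau = 6)
  expect_equal(q_free_rotor(s6, T) / q_free_rotor(s, T), 0.5)
})

test_that("Pitzer-Gwinn limits: free rotor at V0 = 0, HO at large y", {
  T <- 298.15
  s0 <- torsion_from_xy(6, 1e-12, 3, T)   # essentially barrierless
  hr <- q_pitzer_gwinn(s0, T)
  expect_equal(hr$q_class, hr$q_FR, tolerance = 1e-10)   # I0(0) = 1
  expect_equal(hr$q_PG, hr$q_FR * hr$q_HO / hr$q_CHO, tolerance = 1e-10)
  # deep well, M = sigma: q_PG approaches the quantum HO within 5%
  s50 <- torsion_from_xy(10, 50, 3, T)
  hr50 <- q_pitzer_gwinn(s50, T)
  expect_lt(abs(hr50$q_PG / hr50$q_HO - 1), 0.05)
  # very large y must not overflow (scaled Bessel evaluation)
  s_big <- torsion_from_xy(10, 800, 3, T)
  expect_true(is.finite(q_pitzer_gwinn(s_big, T)$q_PG))
})

test_that("PG interpolates the HO and free-rotor limits; Bessel ratio in [0,1)", {
  T <- 298.15
  for (y in c(0.01, 0.5, 2, 10, 50)) {
    s <- torsion_from_xy(8, y, 2, T)
    hr <- q_pitzer_gwinn(s, T)
    # exp(-y/2) I0(y/2) <= 1, so the quantum-corrected free rotor is a
    # strict upper bound; the lower limit holds to the PG model's own
    # interpolation accuracy
    free_lim <- hr$q_FR * hr$q_HO / hr$q_CHO
    expect_lte(hr$q_PG, free_lim * (1 + 1e-12))
    expect_gte(hr$q_PG, min(hr$q_HO, free_lim) * 0.90)
    r <- besselI(y / 2, 1, TRUE) / besselI(y / 2, 0, TRUE)
    expect_gte(r, 0); expect_lt(r, 1)
  }
})

test_that("the torsional eigensolver converges and hits both limits", {
  T <- 400
  # free-rotor limit
  free <- make_torsion_case(V0 = 0, I_r = 3, M = 1, T_grid = T,
                            n_grid = 512)
  qfr <- q_free_rotor(free$spec, T)
  expect_gt(qfr, 5)
  expect_lt(abs(free$oracle$q_exact / qfr - 1), 0.005)
  # harmonic limit: a deep cosine well approaches the bottom-referenced HO
  # at the frequency the barrier relation implies
  # the residual anharmonic shift scales as M^2 hbar^2 / (32 I_r),
  # independently of V0, so a heavy rotor is needed for the 1% window
  deep <- make_torsion_case(V0 = 60, I_r = 30, M = 3, T_grid = T,
                            n_grid = 512)
  expect_lt(abs(deep$oracle$q_exact / q_ho(deep$spec$nu_tau, T) - 1), 0.01)
  # doubling the basis changes nothing at the 1e-8 level
  s <- torsion_from_xy(5, 3, 3, T)
  expect_no_error(torsion_oracle(s, T, 512, check_convergence = TRUE))
})

test_that("PG and the corrected model agree with the eigensolver on the grid", {
  T <- 298.15
  grid <- expand.grid(q_FR = c(2, 6, 20), y = c(0.5, 3, 10), M = c(2, 3))
  for (i in seq_len(nrow(grid))) {
    s <- torsion_from_xy(grid$q_FR[i], grid$y[i], grid$M[i], T)
    qe <- torsion_oracle(s, T, 512)
    expect_lt(abs(q_pitzer_gwinn(s, T)$q_PG / qe - 1), 0.10)
    expect_lt(abs(q_ayala_schlegel(s, T)$q_AS / qe - 1), 0.03)
  }
})

test_that("the polynomial correction tends to 1 and varies smoothly", {
  T <- 1500
  s <- torsion_from_xy(60, 1e-10, 2, T)    # x -> 0, y -> 0
  hr <- q_ayala_schlegel(s, T)
  expect_equal(hr$as_correction, 1, tolerance = 1e-3)
  expect_equal(hr$q_AS / hr$q_PG, hr$as_correction)
  # continuity in T: beyond the smooth first-order variation, successive
  # 0.1 K steps introduce no discontinuities (second differences stay at
  # the curvature level, far below any polynomial-domain seam)
  s2 <- torsion_from_xy(5, 4, 3)
  Ts <- seq(280, 320, by = 0.1)
  q <- vapply(Ts, function(T) q_ayala_schlegel(s2, T)$q_AS, numeric(1))
  expect_lt(max(abs(diff(diff(log(q))))), 1e-6)
})

test_that("hindered-rotor property tables equal derivatives of their ln q", {
  dT <- 0.01
  for (case in list(c(5, 2, 3), c(12, 0.7, 2), c(3, 8, 3))) {
    s <- torsion_from_xy(case[1], case[2], case[3])
    for (T in c(200, 298.15, 550, 1000)) {
      th_pg <- hr_thermo_pg(s, T)
      th_as <- hr_thermo_as(s, T)
      num_U <- function(qfun) {
        Rkcal_ * T^2 *
          (log(qfun(s, T + dT)) - log(qfun(s, T - dT))) / (2 * dT)
      }
      U_pg_num <- num_U(function(s, T) q_pitzer_gwinn(s, T)$q_PG)
      U_as_num <- num_U(function(s, T) q_ayala_schlegel(s, T)$q_AS)
      tab <- th_pg$table
      expect_equal(tab$U[tab$row == "total"], U_pg_num,
                   tolerance = 1e-5)
      tab2 <- th_as$table
      expect_equal(tab2$U[tab2$row == "total_AS"], U_as_num,
                   tolerance = 1e-5)
      # every row satisfies G = H - T S
      expect_equal(tab$G, tab$H - T * tab$S / 1000, tolerance = 1e-9)
      expect_equal(tab2$G, tab2$H - T * tab2$S / 1000, tolerance = 1e-9)
      # component rows recombine into the total: PG = class + QHO - CHO
      for (p in c("U", "S", "G")) {
        expect_equal(tab[[p]][tab$row == "total"],
                     tab[[p]][tab$row == "classical"] +
                     tab[[p]][tab$row == "quantum_HO"] -
                     tab[[p]][tab$row == "classical_HO"],
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("barrierless rows reduce to free-rotor plus HO correction", {
  T <- 298.15
  s <- torsion_from_xy(6, 1e-12, 3, T)
  tab <- hr_thermo_pg(s, T)$table
  # I1(0) = 0, I0(0) = 1: the classical row is the free rotor
  expect_equal(tab$U[tab$row == "classical"], tab$U[tab$row == "free_rotor"],
               tolerance = 1e-8)
  expect_equal(tab$U[tab$row == "free_rotor"], Rkcal_ * T / 2,
               tolerance = 1e-10)
  expect_equal(tab$U[tab$row == "classical_HO"], Rkcal_ * T,
               tolerance = 1e-10)
})

test_that("vibrational composition factorizes over torsions", {
  fx <- make_reaction(synthetic_reaction_spec(barrier = 6, n_side = 5))
  rec <- fx$system$ts
  T <- 350
  # no torsions: identical to the harmonic product over real modes
  expect_equal(compose_vibrational(rec, T, "HO"),
               q_vibrational_HO(rec$frequencies[rec$frequencies > 0], T),
               tolerance = 1e-12)
  # one torsion: HO/PG ratio is exactly the single-mode ratio
  tor <- torsion_spec(nu_tau = rec$frequencies[2], I_r = 2, M = 3,
                      mode_index = 2)
  rec1 <- rec; rec1$torsions <- list(tor)
  r_models <- compose_vibrational(rec1, T, "HO") /
    compose_vibrational(rec1, T, "PG")
  u <- h_ * c_cm_ * tor$nu_tau / (kB_ * T)
  q_ho_mode <- exp(-u / 2) / (1 - exp(-u))
  expect_equal(r_models, q_ho_mode / q_pitzer_gwinn(tor, T)$q_PG,
               tolerance = 1e-10)
  # two independent torsions multiply
  tor2 <- torsion_spec(nu_tau = rec$frequencies[3], I_r = 3, M = 2,
                       mode_index = 3)
  rec2 <- rec; rec2$torsions <- list(tor, tor2)
  lhs <- compose_vibrational(rec2, T, "PG") / compose_vibrational(rec, T, "HO")
  rhs <- (q_pitzer_gwinn(tor, T)$q_PG / q_ho(tor$nu_tau, T)) *
    (q_pitzer_gwinn(tor2, T)$q_PG / q_ho(tor2$nu_tau, T))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # pointing a torsion at the imaginary mode is refused
  bad <- torsion_spec(nu_tau = 100, I_r = 2, M = 3, mode_index = 1)
  rec3 <- rec; rec3$torsions <- list(bad)
  expect_error(compose_vibrational(rec3, T, "PG"), "imaginary")
})
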