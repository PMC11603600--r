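# TST / CVT rate constants, symmetry, tunneling, branching.

test_that("the symmetry factor is the sigma ratio with override precedence", {
  fx <- make_reaction(synthetic_reaction_spec(barrier = 5, n_side = 5))
  sys <- fx$system
  expect_equal(symmetry_factor(sys), 1)
  sys$reactants[[1]]$sigma <- 12L
  expect_equal(symmetry_factor(sys), 12)
  sys$ts$sigma <- 3L
  expect_equal(symmetry_factor(sys), 4)
  sys$sigma_rx_override <- 2
  expect_equal(symmetry_factor(sys), 2)
  # scaling a reactant sigma scales every rate constant linearly
  sys$sigma_rx_override <- NULL
  k1 <- as.numeric(k_tst(sys, 300))
  sys$reactants[[1]]$sigma <- 24L
  expect_equal(as.numeric(k_tst(sys, 300)) / k1, 2, tolerance = 1e-12)
})

test_that("zero activation energy reproduces the universal frequency factor", {
  fx <- make_reaction(synthetic_reaction_spec(molecularity = 1, barrier = 0))
  T <- 298.15
  k <- k_tst(fx$system, T)
  expect_equal(as.numeric(k), kB_ * T / h_, tolerance = 1e-12)
  expect_equal(attr(k, "units"), "s^-1")
  # prefactor is linear in T at fixed (zero) dG
  expect_equal(as.numeric(k_tst(fx$system, 2 * T)) / as.numeric(k), 2,
               tolerance = 1e-12)
})

test_that("a 1 kcal/mol change in dG is a ~5-fold change in k at 298 K", {
  T <- 298
  fx <- make_reaction(synthetic_reaction_spec(barrier = 8, n_side = 5))
  k0 <- k_tst(fx$system, T)
  lowered <- fx$system
  lowered$ts$energy <- lowered$ts$energy - 1 / 627.5094740631
  k1 <- k_tst(lowered, T)
  expect_equal(as.numeric(k1) / as.numeric(k0),
               exp(1000 / (1.9872 * T)), tolerance = 1e-3)
  expect_equal(round(as.numeric(k1) / as.numeric(k0)), 5)
})

test_that("bimolecular unit conversion closes to molecule units", {
  fx <- make_reaction(synthetic_reaction_spec(barrier = 8, n_side = 5))
  T <- 320
  k <- k_tst(fx$system, T)
  expect_equal(attr(k, "units"), "cm^3 molecule^-1 s^-1")
  act <- attr(k, "activation")
  k_M <- kB_ * T / h_ * exp(-act$dG_1M / (Rkcal_ * T))   # L mol^-1 s^-1
  expect_equal(as.numeric(k), k_M * 1000 / NA_, tolerance = 1e-12)
})

test_that("k_gt matches TST at s = 0 and decreases with dG", {
  fx <- make_reaction(synthetic_reaction_spec(barrier = 8, n_side = 20))
  T <- 298.15
  expect_equal(as.numeric(k_gt(fx$system, 0, T)),
               as.numeric(k_tst(fx$system, T)))
  sv <- vapply(fx$system$gts_series, `[[`, numeric(1), "s_value")
  ks <- vapply(sv, function(s) as.numeric(k_gt(fx$system, s, T)), numeric(1))
  dG <- vapply(sv, function(s)
    attr(k_gt(fx$system, s, T), "activation")$dG_1M, numeric(1))
  expect_true(all(diff(ks[order(dG)]) <= 1e-12 * max(ks)))
  expect_error(k_gt(fx$system, 0.123456, T), "no GTS record")
})

test_that("CVT minimization recovers planted Gibbs maxima and bounds TST", {
  T_grid <- c(250, 298.15, 420, 600)
  specs <- list(
    synthetic_reaction_spec(barrier = 8, entropy_shift = 0, seed = 11),
    synthetic_reaction_spec(barrier = 6, entropy_shift = 400, seed = 12),
    synthetic_reaction_spec(barrier = 10, entropy_shift = 900,
                            shift_width = 0.2, seed = 13),
    synthetic_reaction_spec(shape = "eckart", barrier = 9, dE_rxn = -14,
                            entropy_shift = 600, seed = 14))
  for (spec in specs) {
    fx <- make_reaction(spec, T_grid = T_grid)
    for (i in seq_along(T_grid)) {
      cv <- k_cvt(fx$system, T_grid[i])
      expect_equal(cv$s_star, fx$ground_truth$s_star$s_star[i])
      expect_lte(as.numeric(cv$k), as.numeric(cv$k_tst) * (1 + 1e-12))
      # duality: the k-minimizer is the dG-maximizer on the same grid
      expect_equal(cv$curve$s[which.max(cv$curve$dG_1M)],
                   cv$curve$s[which.min(cv$curve$k)])
    }
  }
  # a symmetric barrier with flat frequencies peaks at the saddle point
  fx0 <- make_reaction(synthetic_reaction_spec(barrier = 8, seed = 2))
  cv0 <- k_cvt(fx0$system, 298.15)
  expect_equal(cv0$s_star, 0)
  expect_equal(as.numeric(cv0$k), as.numeric(cv0$k_tst))
})

test_that("entropy-driven peak shifts grow with the planted shift", {
  T <- 600
  shifts <- c(0, 300, 800)
  rf <- vapply(shifts, function(a) {
    fx <- make_reaction(synthetic_reaction_spec(barrier = 8,
                                                entropy_shift = a,
                                                seed = 21), T_grid = T)
    cv <- k_cvt(fx$system, T)
    recrossing_factor(cv$k_tst, cv$k)
  }, numeric(1))
  expect_equal(rf[1], 1)
  expect_true(all(diff(rf) >= 0))
  expect_gt(rf[3], 1)
})

test_that("Eckart transmission has the classical, Wigner and T limits", {
  b <- list(dV1 = 15, dV2 = 12, nu_imag = 1e-4)
  expect_equal(eckart_kappa(b, 300), 1, tolerance = 1e-6)
  # symmetric barrier, small h*nu/kT: Wigner's quadratic law within 1%
  for (u in c(0.1, 0.2, 0.3)) {
    nu <- 400
    T <- h_ * c_cm_ * nu / (kB_ * u)
    kap <- eckart_kappa(list(dV1 = 20, dV2 = 20, nu_imag = nu), T)
    expect_lt(abs(kap / (1 + u^2 / 24) - 1), 0.01)
  }
  # monotone decrease with temperature on a fixed barrier
  b2 <- list(dV1 = 10, dV2 = 14, nu_imag = 1300)
  ks <- vapply(c(220, 298.15, 400, 600, 900), eckart_kappa, numeric(1),
               barrier = b2)
  expect_true(all(diff(ks) < 0))
  expect_true(all(ks > 1))
})

test_that("overall rates and branching ratios are bookkeeping-exact", {
  ks <- c(9.73e-13, 2.3e-14, 3e-15, 1e-15)
  expect_equal(overall_rate(as.list(ks)), sum(ks))
  g <- branching_ratios(ks)
  expect_equal(sum(g), 100, tolerance = 1e-10)
  expect_equal(g, 100 * ks / sum(ks))
  expect_equal(branching_ratios(ks[c(3, 1, 4, 2)]), g[c(3, 1, 4, 2)])
  expect_equal(branching_ratios(c(1, 1)), c(50, 50))
  k1 <- 2; attr(k1, "units") <- "s^-1"
  k2 <- 3; attr(k2, "units") <- "cm^3 molecule^-1 s^-1"
  expect_error(overall_rate(list(k1, k2)), "mixed")
  expect_error(branching_ratios(c(0, 0)), "zero")
})

test_that("compute_rates assembles consistent tables", {
  fx <- make_reaction(synthetic_reaction_spec(barrier = 8, n_side = 20,
                                              entropy_shift = 500, seed = 5))
  res <- compute_rates(fx$system, temperatures = c(298.15, 400, 600),
                       method = "CVT", eckart = TRUE)
  tab <- res$table
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$k_CVT <= tab$k_TST * (1 + 1e-12)))
  expect_true(all(tab$recrossing >= 1 - 1e-12))
  expect_true(all(tab$kappa_Eckart > 1))
  expect_equal(tab$k_CVT_kappa, tab$k_CVT * tab$kappa_Eckart)
  expect_error(compute_rates(fx$system, c(400, 300)), "increasing")
})
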