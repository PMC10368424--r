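test_that("encounter probability limits, monotonicity, and class handling", {
  p <- sim_params()
  expect_equal(encounter_probability(0, p), 0)
  expect_lt(encounter_probability(1e6, p, dt_s = 1e-9), 1e-6)
  d <- c(1e4, 1e5, 1e6, 1e7)
  pe <- encounter_probability(d, p)
  expect_true(all(diff(pe) > 0))
  expect_true(all(pe >= 0 & pe <= 1))
  expect_lt(encounter_probability(1e6, p, dt_s = 30),
            encounter_probability(1e6, p, dt_s = 60))
  # entities with spatial coefficient > 1 encounter more often
  expect_gt(encounter_probability(1e6, p, "size2"),
            encounter_probability(1e6, p, "free"))
  expect_error(encounter_probability(1e6, p, "size9"), "unknown entity class")
})

test_that("encounter formula matches a Brownian random-walk oracle within 3 SE", {
  set.seed(42)
  L <- 25  # one absorbing sphere of radius 5 um per (25 um)^3
  hit <- brownian_hit_fraction(15000, D = 1, R = 5, L = L, t_max = 6,
                               dt = 0.002)
  p <- sim_params(diffusion_um2_s = 1, radius_E_um = 2.5, radius_T_um = 2.5,
                  round_s = 6)
  pe <- encounter_probability((1 / L^3) * 1e12, p, "free", dt_s = 6)
  expect_lt(abs(pe - hit["fraction"]), 3 * hit["se"])
})

test_that("2D constants derive from 3D by the confinement length", {
  bc <- binding_constants()
  k10 <- derive_2d_constants(bc, 10)
  k20 <- derive_2d_constants(bc, 20)
  expect_equal(k20$kon2d_A, k10$kon2d_A / 2)
  expect_equal(k20$koff2d_A, k10$koff2d_A)
  expect_equal(k10$koff2d_A, bc$koff_A)
  expect_equal(k10$koff2d_B, bc$koff_B)
  # dimensional round trip: 1/(M s) -> um^3/(molec s) -> /confinement (um)
  expect_equal(k10$kon2d_A, 1e5 * 1e15 / 6.02214076e23 / 0.01,
               tolerance = 1e-12)
  tiny <- binding_constants(kon_A = 1e-30)
  expect_lt(derive_2d_constants(tiny, 10)$kon2d_A, 1e-35)
  expect_error(derive_2d_constants(bc, 0), "must be > 0")
})

test_that("bond kinetics: empty patch, linear closed form, partner bound", {
  k2d <- derive_2d_constants(binding_constants(), 10)
  params <- sim_params()
  eff0 <- generate_population(1, "effector", expression_spec(1, 0))
  eff0$free_antigen <- 0; eff0$antigen_total <- 0
  tgt0 <- generate_population(1, "target", expression_spec(1, 0))
  tgt0$free_antigen <- 0; tgt0$antigen_total <- 0
  ev <- contact_event(eff0, tgt0, 1, params)
  expect_equal(simulate_bond_formation(ev, k2d), 0)

  # single production channel, negligible dissociation/depletion: N = k*rho1*rho2*Ac*t
  kl <- derive_2d_constants(binding_constants(koff_A = 1e-12,
                                              koff_B = 1e-12), 10)
  t_small <- 1e-6
  n <- bitesim:::bond_counts(0, 10, 20, 0, t_small, kl, 3)
  expected <- kl$kon2d_B / 3 * 10 * 20 * t_small
  expect_equal(n, expected, tolerance = 1e-6)

  # long contact saturates at the lesser side's available partners
  nsat <- bitesim:::bond_counts(50, 10, 5000, 5000, 5, kl, 3)
  expect_lte(nsat, 60 + 1e-9)
  expect_gt(nsat, 55)

  expect_error(contact_event(eff0, tgt0, 100, params), "duration")
})

test_that("bond ODE matches a Gillespie stochastic oracle within 3 SE", {
  k2d <- derive_2d_constants(binding_constants(), 10)
  set.seed(21)
  g <- gillespie_bonds_mean(800, nA = 250, nAY = 0, nB = 0, nYB = 250,
                            konA = k2d$kon2d_A, konB = k2d$kon2d_B,
                            koffA = k2d$koff2d_A, koffB = k2d$koff2d_B,
                            area = 3, t_end = 0.12)
  ode <- bitesim:::bond_counts(250, 0, 0, 250, 0.12, k2d, 3)
  expect_lt(abs(ode - g["mean"]), 3 * g["se"])

  # both channels plus appreciable dissociation
  bc2 <- binding_constants(koff_A = 1, koff_B = 0.5)
  k2 <- derive_2d_constants(bc2, 10)
  g2 <- gillespie_bonds_mean(600, nA = 200, nAY = 100, nB = 300, nYB = 150,
                             konA = k2$kon2d_A, konB = k2$kon2d_B,
                             koffA = 1, koffB = 0.5, area = 3, t_end = 1)
  ode2 <- bitesim:::bond_counts(200, 100, 300, 150, 1, k2, 3)
  expect_lt(abs(ode2 - g2["mean"]), 3 * g2["se"])
})

test_that("adhesion law: closed form, limits, monotonicity", {
  expect_equal(adhesion_probability(0, 0.01), 0)
  expect_equal(adhesion_probability(log(2) / 0.01, 0.01), 0.5)
  expect_equal(adhesion_probability(1e9, 0.01), 1)
  n <- seq(0, 500, by = 50)
  expect_true(all(diff(adhesion_probability(n, 0.003)) > 0))
  expect_gt(adhesion_probability(100, 0.01), adhesion_probability(100, 0.001))
  expect_error(adhesion_probability(-1, 0.01), ">= 0")
  expect_error(adhesion_probability(1, 0), "> 0")
})

test_that("lower CD19 expression gives stochastically lower adhesion probability", {
  params <- sim_params()
  k2d <- derive_2d_constants(params$constants, params$confinement_nm)
  eq <- solve_equilibrium(params$constants, counts_to_molar(5e4, 1e6),
                          counts_to_molar(1.45e5, 1e6), ngml_to_molar(20))
  occA <- eq$AY / eq$A_tot
  occB <- eq$YB / eq$B_tot
  set.seed(5)
  dur <- stats::runif(200, 0.1, 5)
  pa_at <- function(cd19) {
    bitesim:::contact_adhesion_prob(rep(5e4 * (1 - occA), 200),
                                    rep(5e4 * occA, 200),
                                    rep(cd19 * (1 - occB), 200),
                                    rep(cd19 * occB, 200), dur, params, k2d)
  }
  lo <- pa_at(2e4); hi <- pa_at(1.45e5)
  # common random durations: dominance holds contact by contact
  expect_true(all(lo <= hi + 1e-12))
  expect_gt(mean(hi), mean(lo))
})
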