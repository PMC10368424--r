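test_that("population generation: size, degenerate dispersion, reproducibility, mean", {
  spec <- expression_spec(1.45e5, 0.3, "M")
  expect_equal(nrow(generate_population(0, "target", spec)), 0)

  fixed <- generate_population(50, "target", expression_spec(1e5, 0), seed = 1)
  expect_true(all(fixed$antigen_total == 1e5))

  a <- generate_population(200, "effector", spec, seed = 7)
  b <- generate_population(200, "effector", spec, seed = 7)
  expect_identical(a, b)

  big <- generate_population(1e4, "target", spec, seed = 3)
  se <- 1.45e5 * sqrt(exp(0.3^2) - 1) / sqrt(1e4)
  expect_lt(abs(mean(big$antigen_total) - 1.45e5), 3 * se)
  expect_error(expression_spec(-5), "positive")
})

test_that("complex allocation follows bulk occupancy and closes against the bulk", {
  bc <- binding_constants()
  cells <- rbind(generate_population(300, "effector",
                                     expression_spec(5e4, 0.3), seed = 11),
                 generate_population(300, "target",
                                     expression_spec(1.45e5, 0.3), seed = 12))
  # no ligand: all complexes zero
  eq0 <- solve_equilibrium(bc, 1e-9, 1e-9, 0)
  out0 <- allocate_binary_complexes(cells, eq0)
  expect_true(all(out0$binary_complex == 0))

  # near-saturation: free antigen ~ 0 on every cell
  bc_t <- binding_constants(koff_A = 1e-8, koff_B = 1e-8)  # KD = 1e-13
  eqs <- solve_equilibrium(bc_t, 1e-10, 1e-10, 1e-6)
  outs <- allocate_binary_complexes(cells, eqs)
  expect_true(all(outs$free_antigen / outs$antigen_total < 1e-3))

  # summation oracle: allocated counts match bulk complexes within 0.1%
  vol_ml <- 1e-4
  A_tot <- sum(cells$antigen_total[cells$role == "effector"]) / vol_ml *
    1000 / 6.02214076e23
  B_tot <- sum(cells$antigen_total[cells$role == "target"]) / vol_ml *
    1000 / 6.02214076e23
  eq <- solve_equilibrium(bc, A_tot, B_tot, ngml_to_molar(100))
  out <- allocate_binary_complexes(cells, eq)
  alloc_AY <- sum(out$binary_complex[out$role == "effector"])
  bulk_AY <- eq$AY * vol_ml / 1000 * 6.02214076e23
  expect_lt(abs(alloc_AY - bulk_AY) / bulk_AY, 1e-3)
  alloc_YB <- sum(out$binary_complex[out$role == "target"])
  bulk_YB <- eq$YB * vol_ml / 1000 * 6.02214076e23
  expect_lt(abs(alloc_YB - bulk_YB) / bulk_YB, 1e-3)
  # per-cell count conservation
  expect_true(all(out$free_antigen + out$binary_complex <=
                    out$antigen_total * (1 + 1e-12)))
})

test_that("CD3 downregulation: zero at zero complex, plateau by 1 h, step-size robust, monotone", {
  params <- sim_params()
  mk <- function(bound, total = 5e4) {
    cells <- generate_population(1, "effector", expression_spec(total, 0))
    cells$binary_complex <- bound
    cells$free_antigen <- total - bound
    cells
  }
  none <- update_cd3_downregulation(mk(0), 60, params)
  expect_equal(none$antigen_total, 5e4)

  # hold the complex level constant between steps; compare loss in the two hours
  run_held <- function(dt_s, minutes, bound = 500) {
    c0 <- mk(bound)
    traj <- numeric(0)
    for (i in seq_len(minutes * 60 / dt_s)) {
      held <- c0$binary_complex
      c0 <- update_cd3_downregulation(c0, dt_s, params)
      c0$binary_complex <- held  # constant drive
      traj <- c(traj, c0$antigen_total)
    }
    traj
  }
  tr <- run_held(60, 120)
  drop1 <- tr[1] - tr[60]
  drop2 <- tr[60] - tr[120]
  expect_lt(drop2, 0.05 * drop1)          # plateau property
  expect_true(all(diff(tr) <= 1e-9))      # monotone nonincreasing

  coarse <- run_held(60, 30)
  fine <- run_held(1, 30)
  expect_equal(coarse[30], fine[30 * 60], tolerance = 0.02)
  expect_true(all(tr >= 0))
})

test_that("CD19 internalization: identity at dt 0, exact exponential, semigroup", {
  mk <- function(bound) {
    cells <- generate_population(1, "target", expression_spec(1e5, 0))
    cells$binary_complex <- bound
    cells$free_antigen <- 1e5 - bound
    cells
  }
  expect_equal(update_cd19_internalization(mk(1000), 0)$binary_complex, 1000)
  one <- update_cd19_internalization(mk(1000), 1)
  expect_equal(one$binary_complex, 1000 * exp(-0.002), tolerance = 1e-12)
  twice <- update_cd19_internalization(one, 1)
  once2 <- update_cd19_internalization(mk(1000), 2)
  expect_equal(twice$binary_complex, once2$binary_complex, tolerance = 1e-12)
  expect_equal(twice$antigen_total, once2$antigen_total, tolerance = 1e-9)
})
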