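two_organ_system <- function(blood_frac = 0) {
  organ_system(data.frame(
    organ = c("blood", "tissue"),
    volume_ml = c(5000, 1000),
    b_fraction = c(blood_frac, 1 - blood_frac),
    t_fraction = c(0.02, 0.98),
    exposure = c(1, 1),
    forms_is = c(FALSE, TRUE), stringsAsFactors = FALSE))
}

test_that("organ system validation: fractions, volumes, blood guard", {
  os <- organ_system()
  expect_equal(sum(os$b_fraction), 1)
  expect_equal(sum(os$t_fraction), 1)
  expect_false(os$forms_is[os$organ == "blood"])
  bad <- os; bad$b_fraction[2] <- bad$b_fraction[2] + 0.1
  expect_error(organ_system(bad), "sum to 1")
  armed <- os; armed$forms_is[armed$organ == "blood"] <- TRUE
  expect_error(organ_system(armed), "blood compartment cannot form")
})

test_that("cell partitioning conserves totals and honours the repertoire", {
  os <- organ_system()
  part <- partition_cells(5e10, os, "b")
  expect_equal(sum(part$count), 5e10)
  expect_equal(part$count[part$organ == "blood"], 0.02 * 5e10)
  single <- partition_cells(1e6, two_organ_system(0), "b")
  expect_equal(single$count[single$organ == "tissue"], 1e6)
  expect_equal(single$count[single$organ == "blood"], 0)
})

test_that("trafficking releases ~4.17%/h and conserves cell numbers exactly", {
  os <- two_organ_system(blood_frac = 1)  # released cells land in blood
  n <- 1e5
  agents <- data.frame(id = seq_len(n), organ = "tissue",
                       cd19 = rep(3e4, n), state = "free",
                       stringsAsFactors = FALSE)
  st <- bitesim:::invivo_state(agents, weight = 10, organs = os)
  set.seed(31)
  st1 <- traffic_b_cells(st, 1)
  moved <- sum(st1$agents$organ == "blood")
  expect_lt(abs(moved - 0.0417 * n), 3 * sqrt(n * 0.0417 * (1 - 0.0417)))
  expect_equal(nrow(st1$agents), n)

  # exact conservation over 100 steps on the full organ system
  st2 <- bitesim:::invivo_state(
    data.frame(id = 1:2000,
               organ = sample(organ_system()$organ, 2000, replace = TRUE),
               cd19 = 3e4, state = "free", stringsAsFactors = FALSE),
    weight = 1, organs = organ_system())
  for (i in 1:100) st2 <- traffic_b_cells(st2, 1)
  expect_equal(nrow(st2$agents), 2000)
  expect_error(traffic_b_cells(st2, 0.5), "whole hours")
})

test_that("turnover is exact exponential growth with CD19 inheritance", {
  st <- bitesim:::invivo_state(
    data.frame(id = 1:100, organ = "tissue", cd19 = stats::rlnorm(100, 10),
               state = "free", stringsAsFactors = FALSE),
    weight = 1e6, organs = two_organ_system())
  still <- b_cell_turnover(st, patient_profile(growth_per_day = 0), 24)
  expect_equal(still$weight, 1e6)
  grown <- st
  for (d in 1:10) grown <- b_cell_turnover(grown,
                                           patient_profile(growth_per_day = 0.071),
                                           24)
  expect_equal(grown$weight, 1e6 * exp(0.71), tolerance = 1e-12)
  expect_identical(grown$agents$cd19, st$agents$cd19)  # pure inheritance
})

test_that("dose regimens: step-up week, scheme economy, infusion concentration", {
  high1 <- dose_regimen("high", 1, n_weeks = 12)
  expect_equal(high1$weekly_ug_day[1], 9)    # starting dose, cycle 1 week 1
  expect_equal(high1$weekly_ug_day[2], 28)
  expect_equal(high1$weekly_ug_day[5], 0)    # off-week of cycle 1
  expect_equal(high1$weekly_ug_day[7], 28)   # cycle 2 resumes at full dose
  high2 <- dose_regimen("high", 2, n_weeks = 12)
  expect_lt(high2$total_dose_ug, high1$total_dose_ug)
  expect_equal(bitesim:::regimen_concentration(high1, 24 * 8, 1.8),
               28 / (1.8 * 24))
  expect_error(dose_regimen("high", 3), "scheme")
})

test_that("regimen ranking applies the three lexicographic tiers", {
  mk <- function(level, scheme, kill, cd19_ratio, dose) {
    structure(list(
      regimen = structure(list(level = level, scheme = scheme,
                               total_dose_ug = dose),
                          class = "dose_regimen"),
      profile = patient_profile(),
      totals = c(baseline = 1e10, final = 1e10 * 10^-kill,
                 kill_log10 = kill),
      evolution = data.frame(time_h = c(0, 100),
                             mean_cd19 = c(3e4, 3e4 * cd19_ratio))),
      class = "bite_invivo_sim")
  }
  # identical efficacy and evolution: lower total dose wins
  r <- rank_regimens(list(mk("high", 1, 2, 0.8, 2000),
                          mk("medium", 1, 2, 0.8, 1200)))
  expect_equal(r$regimen[1], "medium/scheme1")
  # higher kill wins regardless of dose
  r2 <- rank_regimens(list(mk("medium", 1, 1, 0.9, 1200),
                           mk("high", 1, 3, 0.6, 2000)))
  expect_equal(r2$regimen[1], "high/scheme1")
  # equal kill: less CD19 evolution wins
  r3 <- rank_regimens(list(mk("high", 1, 2, 0.6, 1200),
                           mk("high", 2, 2, 0.9, 2000)))
  expect_equal(r3$regimen[1], "high/scheme2")
  bad <- mk("high", 1, 2, 0.8, 2000)
  bad$profile <- patient_profile(baseline_b_per_ul = 100)
  expect_error(rank_regimens(list(mk("high", 1, 2, 0.8, 2000), bad)),
               "different scenarios")
})

test_that("zero dose leaves B cells growing at the profile rate with no lysis", {
  reg0 <- dose_regimen("low", 1, n_weeks = 1)
  reg0$weekly_ug_day[] <- 0
  prof <- patient_profile(growth_per_day = 0.071)
  cfg <- invivo_config(duration_weeks = 1, n_agents = 500, seed = 5)
  res <- run_invivo(regimen = reg0, profile = prof, config = cfg)
  expect_equal(sum(res$organ_lysis$lysed), 0)
  expect_equal(unname(res$totals["final"] / res$totals["baseline"]),
               exp(0.071 * 7), tolerance = 1e-9)
  expect_equal(res$evolution$mean_cd19[1],
               utils::tail(res$evolution$mean_cd19, 1))
})

test_that("bone marrow is a sanctuary relative to lymph nodes in every replicate", {
  for (seed in 1:3) {
    cfg <- invivo_config(duration_weeks = 1, n_agents = 1200, seed = seed)
    res <- run_invivo(config = cfg)
    ol <- res$organ_lysis
    bm <- ol$lysis_fraction[ol$organ == "bone_marrow"]
    ln <- ol$lysis_fraction[ol$organ == "lymph_nodes"]
    expect_lt(bm, ln)
    expect_equal(ol$lysed[ol$organ == "blood"], 0)  # blood never forms IS
    # systemic survivor CD19 nonincreasing under killing
    expect_lte(utils::tail(res$evolution$mean_cd19, 1),
               res$evolution$mean_cd19[1])
  }
})
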