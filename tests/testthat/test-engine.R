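test_that("entity classification covers the six reachable compositions", {
  expect_equal(classify_entity(1, 1), "ET")
  expect_equal(classify_entity(2, 1), "ETE")
  expect_equal(classify_entity(1, 2), "ETT")
  expect_equal(classify_entity(2, 2), "ETET")
  expect_equal(classify_entity(3, 1), "ETEE")
  expect_equal(classify_entity(1, 3), "ETTT")
  expect_error(classify_entity(4, 0), "not reachable")
  expect_error(classify_entity(0, 2), "not reachable")
  expect_error(classify_entity(3, 2), "not reachable")
  expect_error(classify_entity(2, 2, join_order = c("target", "effector",
                                                    "effector", "target")),
               "join order")
})

test_that("no crosslinker means no engagement; no free targets means no synapses", {
  cfg <- base_config(2e6, bite_ngml = 0, duration_min = 10, replicates = 2,
                     seed = 1)
  res <- run_base(cfg)
  expect_true(all(res$timeseries$effector_engaged == 0))
  expect_equal(nrow(res$entities), 0)

  # effectively no targets in the subvolume
  cfg2 <- base_config(1e5, et_ratio = 1e6, bite_ngml = 100,
                      duration_min = 10, replicates = 1, seed = 2)
  res2 <- run_base(cfg2)
  expect_equal(nrow(res2$entities), 0)
})

test_that("forced saturation pairs every cell into a typical synapse in round 1", {
  # diffusion high enough that P_e ~ 1, alpha high enough that P_a ~ 1
  p <- sim_params(diffusion_um2_s = 1e8, alpha = 1e3)
  cfg <- base_config(2e6, et_ratio = 1, bite_ngml = 100, duration_min = 1,
                     replicates = 1, seed = 3, params = p)
  res <- run_base(cfg)
  fin <- res$timeseries[nrow(res$timeseries), ]
  expect_equal(fin$effector_engaged, 1)
  expect_equal(fin$target_engaged, 1)
  expect_true(all(res$entities$label == "ET"))
})

test_that("identical seeds reproduce identical histories; invariants hold", {
  cfg <- base_config(2e6, bite_ngml = 100, duration_min = 30, replicates = 2,
                     seed = 11)
  a <- run_base(cfg)
  b <- run_base(cfg)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$entities, b$entities)

  sizes <- a$entities$e + a$entities$t
  expect_true(all(sizes >= 2 & sizes <= 4))
  expect_true(all(a$entities$label ==
                    mapply(classify_entity, a$entities$e, a$entities$t)))
  # engagement counts close against entity membership per replicate
  for (r in unique(a$timeseries$replicate)) {
    ent_r <- a$entities[a$entities$replicate == r, ]
    fin <- a$timeseries[a$timeseries$replicate == r, ]
    fin <- fin[nrow(fin), ]
    n_eff <- round(cfg$effector_density_per_ml * cfg$scaled_volume_ul * 1e-3)
    expect_equal(fin$effector_engaged * n_eff, sum(ent_r$e))
  }
})

test_that("engagement grows over time and flattens toward 60 min", {
  cfg <- base_config(2e6, bite_ngml = 100, duration_min = 60,
                     replicates = 10, seed = 13)
  res <- run_base(cfg)
  s <- res$summary
  expect_true(all(diff(s$effector_engaged) >= -1e-12))  # nondecreasing mean
  first_half <- s$effector_engaged[s$time_min == 30] -
    s$effector_engaged[s$time_min == 0]
  second_half <- s$effector_engaged[s$time_min == 60] -
    s$effector_engaged[s$time_min == 30]
  expect_lt(second_half, first_half)  # concave trend
})

test_that("variant summaries: degenerate cases and share closure", {
  ents <- data.frame(e = c(1, 1), t = c(1, 1), label = c("ET", "ET"))
  sv <- summarize_variants(ents)
  expect_equal(sv$variant_fraction, 0)
  expect_equal(sv$median_et_all, 1)

  ents2 <- data.frame(e = c(2, 1), t = c(1, 2), label = c("ETE", "ETT"))
  sv2 <- summarize_variants(ents2)
  expect_equal(sv2$variant_fraction, 1)
  expect_equal(unname(sv2$composition[c("ETE", "ETT")]), c(0.5, 0.5))
  expect_equal(sum(sv2$composition), 1)

  empty <- summarize_variants(data.frame(e = integer(0), t = integer(0),
                                         label = character(0)))
  expect_equal(empty$n_entities, 0)
  expect_true(is.na(empty$variant_fraction))
})

test_that("engagement is monotone in CD19 expression and total cell density", {
  eng <- function(cfg) unname(final_engagement_pct(run_base(cfg))["eff"])
  by_cd19 <- vapply(c("L", "M", "H"), function(l)
    eng(base_config(2e6, cd19 = l, bite_ngml = 20, replicates = 8,
                    seed = 6)), 1)
  expect_true(all(diff(by_cd19) > 0))
  by_density <- vapply(c(1e6, 2e6, 4e6, 8e6), function(d)
    eng(base_config(d, bite_ngml = 100, replicates = 6, seed = 7)), 1)
  expect_true(all(diff(by_density) > 0))
})
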