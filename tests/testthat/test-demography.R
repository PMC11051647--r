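test_that("density-dependent death rate follows the stated formula", {
  expect_equal(density_dependent_death_rate(0.03, d = 0, s = 7500, k = 0.1),
               0.9 * 0.03)
  expect_equal(density_dependent_death_rate(0.03, d = 7500, s = 7500,
                                            k = 0.37), 0.03)
  expect_equal(density_dependent_death_rate(0.02, d = 3750, s = 7500,
                                            k = 0.1), 0.019)
  expect_error(density_dependent_death_rate(0.02, d = -1, s = 10), ">= 0")
  expect_error(density_dependent_death_rate(0.02, d = 1, s = 0), "> 0")
})

test_that("goal-seek finds a stationary adult death rate", {
  gs <- goal_seek_natural_mortality(standard_config())
  expect_lt(abs(gs$growth_residual), 1e-8)
  expect_gt(gs$ms_female, 0)
  expect_lt(gs$ms_female, 0.2)
  # males must die faster to hold a 2:1 female:male standing ratio under
  # equal recruitment
  expect_gt(gs$ms_male, gs$ms_female)

  # a lower birth rate must be matched by a lower death rate
  slow <- standard_config(demography = list(interlarval_period = 20))
  gs2 <- goal_seek_natural_mortality(slow)
  expect_lt(gs2$ms_female, gs$ms_female)
})

test_that("goal-seek rejects an inconsistent parameter set", {
  bad <- standard_config(demography = list(interlarval_period = 2000))
  expect_error(goal_seek_natural_mortality(bad), "inconsistent")
})

test_that("the engine is stationary at SNCC with the solved rates", {
  cfg <- cfg_std()
  g <- large_grid(3, 3)
  st <- population_state(g, cfg, "naive")
  ops <- simulation_operators(g, cfg)
  for (i in 1:250) st <- run_day(st, g, cfg, ops = ops)
  fem <- rowSums(st$F)
  mal <- rowSums(st$M)
  expect_equal(fem, rep(500, 9), tolerance = 1e-8)
  expect_equal(mal, rep(250, 9), tolerance = 1e-8)
})

test_that("a population seeded below SNCC grows back toward it", {
  cfg <- cfg_std()
  g <- large_grid(1, 1)
  st <- population_state(g, cfg, "naive")
  st$F <- st$F / 2
  st$M <- st$M / 2
  st$P <- st$P / 2
  ops <- simulation_operators(g, cfg)
  start <- sum(st$F)
  for (i in 1:400) st <- run_day(st, g, cfg, ops = ops)
  expect_gt(sum(st$F), start)
  expect_lt(sum(st$F), 500 * 1.001)
})

test_that("class equilibria reproduce the SNCC and order by habitat", {
  cfg <- cfg_std()
  eq <- lapply(c(1, 1.05, 1.10, 1.20), class_equilibrium, config = cfg)
  f <- vapply(eq, `[[`, numeric(1), "females")
  expect_equal(f[1], 5000, tolerance = 1e-9)
  expect_equal(eq[[1]]$males, 2500, tolerance = 1e-9)
  expect_true(all(diff(f) < 0))
  expect_equal(f[4], 0)
  # per-cell medium-river capacity printed for the standard run
  expect_equal(eq[[2]]$females * 0.07, 184, tolerance = 0.01)
  expect_equal(eq[[2]]$males * 0.07, 92, tolerance = 0.01)
})

test_that("class equilibrium matches a long no-movement simulation", {
  cfg <- cfg_std()
  g <- build_schematic_map(list(r = rbind(c(1, 1), c(1, 10))), 1, 10,
                           operational_margin = 0)
  cfg2 <- prepare_config(standard_config(mobility = list(enabled = FALSE)))
  st <- population_state(g, cfg2, "equilibrium")
  ops <- simulation_operators(g, cfg2)
  before <- baseline_population(st)
  for (i in 1:300) st <- run_day(st, g, cfg2, ops = ops)
  after <- baseline_population(st)
  expect_equal(after, before, tolerance = 1e-8)
})

test_that("carrying capacity is linear in cover and in SNCC", {
  cfg <- cfg_std()
  g <- mixed_grid()
  base <- carrying_capacity(g, cfg)

  hab2 <- habitat_classes(cover = c(0.20, 0.14, 0.08, 0.02))
  g2 <- g
  g2$habitat <- hab2
  cc2 <- carrying_capacity(g2, cfg)
  expect_equal(cc2$females, 2 * base$females, tolerance = 1e-9)
  expect_equal(cc2$males, 2 * base$males, tolerance = 1e-9)

  cfg3 <- standard_config(demography = list(sncc_female = 10000,
                                            sncc_male = 5000))
  cc3 <- carrying_capacity(g, cfg3)
  expect_equal(cc3$females, 2 * base$females, tolerance = 1e-6)
})

test_that("large-river cells carry 500 females and 250 males", {
  cc <- carrying_capacity(large_grid(2, 2), cfg_std())
  expect_equal(cc$females, rep(500, 4), tolerance = 1e-9)
  expect_equal(cc$males, rep(250, 4), tolerance = 1e-9)
  # interfluve equilibrium is extinction
  gi <- build_schematic_map(list(), 2, 2)
  cci <- carrying_capacity(gi, cfg_std())
  expect_equal(cci$females, rep(0, 4))
})

test_that("larviposition follows the configured schedule", {
  cfg <- cfg_std()
  g <- large_grid(1, 1)
  st <- population_state(g, cfg, "empty")
  st$F[1, 16:100] <- 10   # 850 mature females
  st <- larviposition_step(st, cfg)
  expect_equal(sum(st$P[, 1]), 850 / 10)   # smeared: 1/interlarval per day

  # synchronized mode: every female aged exactly at first larviposition
  cfg_sync <- prepare_config(
    standard_config(demography = list(larviposition = "synchronized")))
  st2 <- population_state(g, cfg_sync, "empty")
  st2$F[1, 16] <- 1000
  st2 <- larviposition_step(st2, cfg_sync)
  expect_equal(sum(st2$P[, 1]), 1000)

  # males alone produce nothing
  st3 <- population_state(g, cfg, "empty")
  st3$M[1, ] <- 50
  st3 <- larviposition_step(st3, cfg)
  expect_equal(sum(st3$P), 0)
})

test_that("mortality never creates flies; births and emergence never
           destroy them", {
  cfg <- cfg_std()
  g <- mixed_grid()
  st <- population_state(g, cfg, "naive")
  st2 <- natural_mortality_step(st, g, cfg)
  expect_true(all(st2$F <= st$F + 1e-12))
  expect_true(all(st2$M <= st$M + 1e-12))
  expect_true(all(st2$P <= st$P + 1e-12))

  tot_adults <- sum(st2$F) + sum(st2$M)
  st3 <- larviposition_step(st2, cfg)
  expect_equal(sum(st3$F) + sum(st3$M), tot_adults)
  expect_gte(sum(st3$P), sum(st2$P))

  pd <- ncol(st3$P)
  mature <- sum(st3$P[, pd])
  st4 <- emergence_step(st3, cfg)
  expect_equal(sum(st4$F) + sum(st4$M), tot_adults + mature,
               tolerance = 1e-12)
})

test_that("empty cells stay empty under mortality", {
  cfg <- cfg_std()
  g <- mixed_grid()
  st <- population_state(g, cfg, "empty")
  st2 <- natural_mortality_step(st, g, cfg)
  expect_true(all(st2$F == 0) && all(st2$P == 0))
})
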