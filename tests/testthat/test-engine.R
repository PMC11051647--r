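test_that("the fused daily loop matches the composed step functions", {
  cfg <- cfg_std()
  g <- mixed_grid()
  ops <- simulation_operators(g, cfg)
  rc <- river_cells(g, "main")
  plan <- deployment_plan(rc$cell[5:15], start_day = 1, end_day = 400)

  st_ref <- population_state(g, cfg, "naive")
  st_ref$day <- 0
  for (i in 1:25) st_ref <- run_day(st_ref, g, cfg, plan = plan, ops = ops)

  st0 <- population_state(g, cfg, "naive")
  run <- run_simulation(st0, g, cfg, plans = plan, days = 25,
                        record_cells = rc$cell)
  st_fast <- run$final_state
  expect_equal(st_fast$F, st_ref$F, tolerance = 1e-12)
  expect_equal(st_fast$M, st_ref$M, tolerance = 1e-12)
  expect_equal(st_fast$P, st_ref$P, tolerance = 1e-12)
  expect_equal(run$records$pupae_deposited[25], attr(st_ref, "larvae"),
               tolerance = 1e-12)
  expect_equal(run$records$females[25], sum(st_ref$F), tolerance = 1e-12)
})

test_that("identical configurations give bit-identical records", {
  cfg <- cfg_std()
  g <- mixed_grid()
  rc <- river_cells(g, "main")
  plan <- deployment_plan(rc$cell[5:15], 1, 400)
  st <- population_state(g, cfg, "naive")
  r1 <- run_simulation(st, g, cfg, plans = plan, days = 30)
  r2 <- run_simulation(st, g, cfg, plans = plan, days = 30)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$cell_adults, r2$cell_adults)
})

test_that("swapping natural mortality and control changes the outcome", {
  cfg <- cfg_std()
  g <- large_grid(3, 3)
  ops <- simulation_operators(g, cfg)
  plan <- deployment_plan(cell_index(g, 2, 2), 1, 400, schedule = 0.5)

  in_order <- function(swap) {
    st <- population_state(g, cfg, "naive")
    for (i in 1:10) {
      st <- age_step(st)
      if (swap) st <- control_step(st, g, plan)
      st <- natural_mortality_step(st, g, ops = ops)
      st <- movement_step(st, g, ops = ops)
      if (!swap) st <- control_step(st, g, plan)
      st <- larviposition_step(st, cfg)
      st <- emergence_step(st, cfg)
    }
    st
  }
  a <- in_order(FALSE)
  b <- in_order(TRUE)
  expect_false(isTRUE(all.equal(a$F, b$F, tolerance = 1e-12)))
})

test_that("an equilibrium state is a fixed point of the daily cycle", {
  cfg <- cfg_std()
  g <- large_grid(3, 3)
  st <- population_state(g, cfg, "naive")
  before <- baseline_population(st)
  st2 <- run_day(st, g, cfg)
  expect_equal(baseline_population(st2), before, tolerance = 1e-6)
})

test_that("without deaths the population changes only by births", {
  cfg <- prepare_config(standard_config(
    demography = list(ms_female = 0, ms_male = 0,
                      pupal_mortality_sncc = 0)))
  g <- large_grid(3, 3)
  st <- population_state(g, cfg, "empty")
  st$F[, 20:40] <- 1
  st$M[, 20:40] <- 1
  tot0 <- sum(st$F) + sum(st$M) + sum(st$P)
  born <- 0
  ops <- simulation_operators(g, cfg)
  for (i in 1:20) {
    st <- run_day(st, g, cfg, ops = ops)
    born <- born + attr(st, "larvae")
  }
  expect_gt(born, 0)
  expect_equal(sum(st$F) + sum(st$M) + sum(st$P), tot0 + born,
               tolerance = 1e-12)
})

test_that("burn-in on a homogeneous map converges to the SNCC", {
  cfg <- cfg_std()
  g <- large_grid(4, 4)
  st <- burn_in(g, cfg, max_iter = 400)
  expect_lt(attr(st, "max_rel_change"), 1e-6)
  expect_equal(rowSums(st$F), rep(500, 16), tolerance = 1e-6)
  expect_equal(rowSums(st$M), rep(250, 16), tolerance = 1e-6)
})

test_that("with no rivers the population collapses toward zero", {
  cfg <- cfg_std()
  g <- build_schematic_map(list(), 4, 4)
  st <- population_state(g, cfg, "naive")
  seed_tot <- sum(baseline_population(st))
  st <- suppressWarnings(burn_in(g, cfg, max_iter = 2500))
  expect_lt(sum(baseline_population(st)), 0.05 * seed_tot)
})

test_that("an empty deployment plan reproduces the uncontrolled run", {
  cfg <- cfg_std()
  g <- mixed_grid()
  st <- population_state(g, cfg, "naive")
  plan <- deployment_plan(integer(0), 1, 60)
  r0 <- run_simulation(st, g, cfg, plans = NULL, days = 40)
  r1 <- run_simulation(st, g, cfg, plans = plan, days = 40)
  expect_equal(r1$final_state$F, r0$final_state$F, tolerance = 1e-13)
  expect_equal(r1$records$females, r0$records$females, tolerance = 1e-13)
})

test_that("scenarios carry state across phases and reject overlaps", {
  cfg <- cfg_std()
  g <- mixed_grid()
  rc <- river_cells(g, "main")
  st <- population_state(g, cfg, "naive")
  p1 <- deployment_plan(rc$cell[5:11], 1, 30, name = "p1")
  p2 <- deployment_plan(rc$cell[5:20], 41, 70, name = "p2")
  sc <- run_scenario(g, cfg, list(p1, p2), state = st,
                     record_cells = rc$cell)
  expect_named(sc$phases, c("p1", "p2"))
  # the gap between phases is simulated: phase 2 starts from day 40
  expect_equal(min(sc$phases$p2$records$day), 41)
  expect_equal(max(sc$phases$p1$records$day), 30)
  # state carried over: phase-2 start population equals phase-1 end after
  # the uncontrolled gap
  expect_lt(abs(sc$phases$p2$records$females[1] -
                sc$phases$p1$records$females[30]) /
            sc$phases$p1$records$females[30], 0.05)
  bad <- deployment_plan(rc$cell[5:11], 25, 50)
  expect_error(run_scenario(g, cfg, list(p1, bad), state = st),
               "overlap")
})
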