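test_that("percent remaining is 100 without control and 0 when emptied", {
  cfg <- cfg_std()
  g <- large_grid(3, 3)
  st <- population_state(g, cfg, "naive")
  base <- baseline_population(st)
  run <- run_simulation(st, g, cfg, days = 30)
  pr <- percent_remaining(run, base, window = run$days)
  expect_equal(pr$pct_remaining, rep(100, 9), tolerance = 1e-6)

  st2 <- st
  st2$F[5, ] <- 0
  st2$M[5, ] <- 0
  st2$P[5, ] <- 0
  # movement refills an emptied cell, so hold flies still for this check
  cfg_nm <- prepare_config(standard_config(mobility = list(enabled = FALSE)))
  run2 <- run_simulation(st2, g, cfg_nm, days = 5)
  pr2 <- percent_remaining(run2, base, window = run2$days)
  expect_equal(pr2$pct_remaining[5], 0)
})

test_that("a zero-baseline cell reports a missing percentage", {
  cfg <- cfg_std()
  g <- large_grid(2, 2)
  st <- population_state(g, cfg, "naive")
  run <- run_simulation(st, g, cfg, days = 3)
  base <- baseline_population(st)
  base[2] <- 0
  pr <- percent_remaining(run, base, window = run$days)
  expect_true(is.na(pr$pct_remaining[2]))
  expect_false(anyNA(pr$pct_remaining[-2]))
})

test_that("percent remaining over a window is the mean of sub-windows", {
  cfg <- cfg_std()
  g <- mixed_grid()
  rc <- river_cells(g, "main")
  st <- population_state(g, cfg, "naive")
  base <- baseline_population(st)
  plan <- deployment_plan(rc$cell[5:15], 1, 100)
  run <- run_simulation(st, g, cfg, plans = plan, days = 40)
  w1 <- run$days[1:20]
  w2 <- run$days[21:40]
  p_all <- percent_remaining(run, base, window = run$days)
  p1 <- percent_remaining(run, base, window = w1)
  p2 <- percent_remaining(run, base, window = w2)
  expect_equal(p_all$pct_remaining,
               (p1$pct_remaining + p2$pct_remaining) / 2,
               tolerance = 1e-12)
})

test_that("age fractions honour threshold, comparator and sex", {
  cfg <- cfg_std()
  g <- large_grid(2, 2)
  st <- population_state(g, cfg, "empty")
  st$F[, 1] <- 10
  expect_equal(age_fraction(st, threshold = 40, comparator = ">"), 0)
  expect_equal(age_fraction(st, threshold = 1, comparator = ">="), 100)
  st$F[, 50] <- 10
  expect_equal(age_fraction(st, threshold = 40, comparator = ">",
                            sex = "female"), 50)
  expect_true(is.na(age_fraction(st, sex = "male")))
  # equilibrium age structure: the share of old females is moderate
  st2 <- population_state(g, cfg, "naive")
  old <- age_fraction(st2, threshold = 40, comparator = ">",
                      sex = "female")
  expect_gt(old, 10)
  expect_lt(old, 60)
})

test_that("pupal production is steady at equilibrium and missing when
           femaleless", {
  cfg <- cfg_std()
  g <- large_grid(3, 3)
  st <- population_state(g, cfg, "naive")
  run <- run_simulation(st, g, cfg, days = 50)
  ppr <- pupal_production_rate(run)
  daily <- 1000 * run$records$pupae_deposited / run$records$females
  expect_lt(diff(range(daily)), 1e-6)
  expect_equal(ppr, daily[1], tolerance = 1e-9)

  st0 <- population_state(g, cfg, "empty")
  run0 <- run_simulation(st0, g, cfg, days = 3)
  expect_true(is.na(pupal_production_rate(run0)))
})

test_that("transects are ordered source to mouth and cover the river", {
  cfg <- cfg_std()
  g <- mixed_grid()
  rc <- river_cells(g, "main")
  st <- population_state(g, cfg, "naive")
  base <- baseline_population(st)
  run <- run_simulation(st, g, cfg, days = 10)
  pr <- percent_remaining(run, base, window = run$days)
  tr <- transect(g, "main", pr)
  expect_equal(nrow(tr), nrow(rc))
  expect_equal(tr$position, seq_len(nrow(rc)))
  expect_equal(tr$pct_remaining, rep(100, nrow(rc)), tolerance = 0.1)
  expect_error(transect(g, "nope", pr), "unknown river")
})

test_that("tidiers return well-formed tibbles", {
  cfg <- cfg_std()
  g <- large_grid(2, 2)
  st <- population_state(g, cfg, "naive")
  run <- run_simulation(st, g, cfg, days = 5)
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  tdc <- tidy(run, cells = TRUE)
  expect_equal(nrow(tdc), 5 * 4)
  gl <- glance(run)
  expect_equal(gl$days, 5)
  tg <- tidy(g)
  expect_equal(nrow(tg), 4)
  expect_s3_class(autoplot(g), "ggplot")
  expect_s3_class(autoplot(run), "ggplot")
})
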