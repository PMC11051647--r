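# Monte-Carlo oracle: mean Euclidean displacement of a lazy orthogonal walk
mc_walk_displacement <- function(p, steps, walkers = 1e5) {
  moves <- matrix(sample.int(5L, walkers * steps, replace = TRUE,
                             prob = c(1 - p, rep(p / 4, 4))),
                  walkers, steps)
  dx <- rowSums(moves == 2L) - rowSums(moves == 3L)
  dy <- rowSums(moves == 4L) - rowSums(moves == 5L)
  mean(sqrt(dx^2 + dy^2))
}

test_that("exact walk displacement matches a Monte-Carlo oracle", {
  set.seed(421)
  for (p in c(0.15, 0.5)) {
    expect_equal(mean_walk_displacement(p, 30), mc_walk_displacement(p, 30),
                 tolerance = 0.01)
  }
})

test_that("evacuation calibration hits the diffusive target", {
  expect_equal(calibrate_evacuation(0), 0)
  p <- calibrate_evacuation(0.4, 30)
  expect_equal(mean_walk_displacement(p, 30), 0.4 * sqrt(30),
               tolerance = 1e-6)
  # strictly increasing in the nominal displacement
  ps <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5), calibrate_evacuation,
               numeric(1), horizon = 30)
  expect_true(all(diff(ps) > 0))
  expect_error(calibrate_evacuation(5, 30), "unattainable")
})

test_that("the evacuation table ramps with age and halves for males", {
  cfg <- cfg_std()
  et <- list(female = cfg$derived$evac_female,
             male = cfg$derived$evac_male)
  expect_true(all(diff(et$female[1:10]) > 0))
  expect_equal(et$female[10:100], rep(et$female[10], 91))
  expect_equal(et$male[5], calibrate_evacuation(
    0.5 * (0.2 + 4 / 9 * 0.2), 30), tolerance = 1e-8)
  expect_true(all(et$male < et$female))
})

test_that("directional damping follows habitat cover", {
  g <- mixed_grid()
  cfg <- cfg_std()
  rc <- river_cells(g, "main")
  # large -> medium along the main river (downstream cell 29 is large)
  large <- rc$cell[rc$class == "large_river"][1]
  med_up <- rc$cell[match(large, rc$cell) - 1]    # medium neighbour upstream
  expect_equal(directional_factor(g, large, med_up, cfg), 0.7)
  expect_equal(directional_factor(g, med_up, large, cfg), 1)
  # river -> interfluve and back
  cc <- cell_coords(g, med_up)
  inter <- cell_index(g, cc$row - 1, cc$col)
  expect_equal(directional_factor(g, med_up, inter, cfg), 0.01)
  expect_equal(directional_factor(g, inter, med_up, cfg), 1)
  # interfluve -> interfluve undamped
  inter2 <- cell_index(g, cc$row - 2, cc$col)
  expect_equal(directional_factor(g, inter, inter2, cfg), 1)
  # medium -> small damped by the cover ratio (the tributary advances the
  # main river's distance-from-source, so the class break sits at col 8)
  expect_equal(directional_factor(
    g, rc$cell[7], rc$cell[6], cfg), 0.04 / 0.07)
  expect_error(directional_factor(g, rc$cell[1], rc$cell[3], cfg),
               "adjacent")
})

test_that("movement splits outflow equally over four directions", {
  g <- large_grid(5, 5)
  cfg <- cfg_std()
  ops <- simulation_operators(g, cfg)
  ops$evac_female[] <- 0.2
  ops$evac_male[] <- 0
  st <- population_state(g, cfg, "empty")
  centre <- cell_index(g, 3, 3)
  st$F[centre, 20] <- 100
  st2 <- movement_step(st, g, ops = ops)
  nb <- cell_index(g, c(2, 4, 3, 3), c(3, 3, 2, 4))
  expect_equal(st2$F[nb, 20], rep(100 * 0.2 / 4, 4))
  expect_equal(st2$F[centre, 20], 80)
})

test_that("movement conserves each sex-age cohort to machine precision", {
  g <- mixed_grid()
  cfg <- cfg_std()
  ops <- simulation_operators(g, cfg)
  set.seed(99)
  st <- population_state(g, cfg, "empty")
  st$F[] <- runif(length(st$F))
  st$M[] <- runif(length(st$M))
  colF <- colSums(st$F)
  colM <- colSums(st$M)
  for (i in 1:5) st <- movement_step(st, g, ops = ops)
  expect_equal(colSums(st$F), colF, tolerance = 1e-13)
  expect_equal(colSums(st$M), colM, tolerance = 1e-13)
})

test_that("flux along a river dwarfs flux into the interfluve", {
  g <- mixed_grid()
  cfg <- cfg_std()
  ops <- simulation_operators(g, cfg)
  rc <- river_cells(g, "main")
  mid <- rc$cell[10]
  st <- population_state(g, cfg, "empty")
  st$F[mid, 20] <- 1000
  st2 <- movement_step(st, g, ops = ops)
  cc <- cell_coords(g, mid)
  along <- st2$F[cell_index(g, cc$row, cc$col + 1), 20]
  cross <- st2$F[cell_index(g, cc$row + 1, cc$col), 20]
  expect_equal(along / cross, 1 / 0.01, tolerance = 1e-9)
})

test_that("a symmetric state on a symmetric map stays symmetric", {
  g <- build_schematic_map(list(r = rbind(c(3, 1), c(3, 11))), 5, 11,
                           operational_margin = 0)
  cfg <- cfg_std()
  ops <- simulation_operators(g, cfg)
  st <- population_state(g, cfg, "naive")
  for (i in 1:10) st <- run_day(st, g, cfg, ops = ops)
  pool <- matrix(baseline_population(st), 5, 11)
  # mirror symmetry across the river row and across the middle column
  expect_equal(pool, pool[5:1, ], tolerance = 1e-12)
})
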