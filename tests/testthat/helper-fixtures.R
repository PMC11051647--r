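# Shared fixtures, memoised so the goal-seek and evacuation calibration run
# once per test session.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

cfg_std <- function() memo("cfg_std", prepare_config(standard_config()))

# a small mixed landscape: one long river (small -> medium -> large) with a
# tributary, crossing a 12 x 40 grid
mixed_grid <- function() memo("mixed_grid", {
  build_schematic_map(
    list(main = rbind(c(6, 2), c(6, 39)),
         trib = rbind(c(2, 5), c(6, 5))),
    nrow = 12, ncol = 40, operational_margin = 1
  )
})

large_grid <- function(nr = 5, nc = 5) {
  memo(paste0("large_grid_", nr, "_", nc), homogeneous_grid(nr, nc))
}

# uniform all-large equilibrium state on a small homogeneous map
large_eq_state <- function(nr = 5, nc = 5) {
  population_state(large_grid(nr, nc), cfg_std(), "naive")
}
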