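#' Kill schedule of a Tiny Target
#'
#' Age- and sex-dependent daily kill rates per target at a density of one
#' target per km2 of habitat.  The base schedule (Schedule 0.05) kills
#' 0.01 percent of one-day-old females per day, rising linearly to 0.05
#' percent at age 10 days and constant thereafter; males of any age are
#' killed at 80 percent of the female rate.  Other schedules scale every
#' sex- and age-specific rate by a set proportion and are named after their
#' rate for females >= 10 days old: `kill_schedule(0.01)` kills 0.01
#' percent of old females per day.
#'
#' @param name_rate Daily percent kill of females aged >= 10 days at unit
#'   target density (the schedule's name; standard 0.05).
#' @param max_adult_age Number of adult daily age classes.
#' @return Object of class `kill_schedule`: name rate plus per-age rate
#'   vectors (`rate_female`, `rate_male`, daily fractions at one target per
#'   km2 habitat).
#' @examples
#' s <- kill_schedule(0.05)
#' s$rate_female[10] * 100  # 0.05 percent per day
#' @export
kill_schedule <- function(name_rate = 0.05, max_adult_age = 100) {
  stopifnot(name_rate >= 0, max_adult_age >= 10)
  a <- seq_len(max_adult_age)
  base <- (1e-4 + (pmin(a, 10) - 1) / 9 * (5e-4 - 1e-4)) * name_rate / 0.05
  structure(list(name_rate = name_rate,
                 rate_female = base,
                 rate_male = 0.8 * base),
            class = "kill_schedule")
}

#' @export
print.kill_schedule <- function(x, ...) {
  cat("<kill_schedule ", format(x$name_rate), "> old-female kill ",
      x$name_rate, "% per target per km2 habitat per day\n", sep = "")
  invisible(x)
}

#' Residual efficacy of a degrading target
#'
#' Targets lose killing power by a first-order process: after `days` days
#' the efficacy multiplier is `(1 - degradation_rate)^days`.  At the
#' standard 1.5 percent per day the efficacy is about 6 percent of the
#' initial level after six months (183 days).
#'
#' @param days Days since deployment (>= 0).
#' @param degradation_rate Daily fractional decline in \[0, 1\].
#' @return Efficacy multiplier(s) in (0, 1\].
#' @examples
#' degraded_efficacy(183, 0.015)
#' @export
degraded_efficacy <- function(days, degradation_rate) {
  stopifnot(all(days >= 0), degradation_rate >= 0, degradation_rate <= 1)
  (1 - degradation_rate)^days
}

#' A Tiny-Target deployment plan
#'
#' Where, when and how densely targets are deployed.  Targets go only into
#' riverine cells, 20 per cell as standard; they degrade at
#' `degradation_rate` per day and the whole set is replaced by fresh
#' targets at the beginning of the 184th day of each cycle (every
#' `refresh_period` = 183 days) for as long as the plan runs.
#'
#' @param cells Cell ids of the treated cells.
#' @param start_day First day of control (day numbering of the run).
#' @param end_day Last day of control.
#' @param schedule A [kill_schedule()] or its numeric name rate.
#' @param targets_per_cell Targets deployed per treated cell (standard 20).
#' @param degradation_rate Daily efficacy decline (standard 0.015).
#' @param refresh_period Days between deployments (standard 183).
#' @param name Optional label for reporting.
#' @return Object of class `deployment_plan`.
#' @export
deployment_plan <- function(cells, start_day, end_day,
                            schedule = 0.05, targets_per_cell = 20,
                            degradation_rate = 0.015, refresh_period = 183,
                            name = NULL) {
  if (is.numeric(schedule)) schedule <- kill_schedule(schedule)
  stopifnot(inherits(schedule, "kill_schedule"),
            targets_per_cell >= 0,
            degradation_rate >= 0, degradation_rate <= 1,
            refresh_period >= 1, end_day >= start_day)
  structure(list(cells = as.integer(cells), start_day = start_day,
                 end_day = end_day, schedule = schedule,
                 targets_per_cell = targets_per_cell,
                 degradation_rate = degradation_rate,
                 refresh_period = refresh_period,
                 name = name %||% "plan"),
            class = "deployment_plan")
}

#' @export
print.deployment_plan <- function(x, ...) {
  cat("<deployment_plan '", x$name, "'> ", length(x$cells),
      " treated cells, days ", x$start_day, "-", x$end_day,
      ", schedule ", x$schedule$name_rate, ", degradation ",
      100 * x$degradation_rate, "%/day\n", sep = "")
  invisible(x)
}

#' Target density per km2 of habitat in treated cells
#'
#' Targets are deployed per cell but act within the cell's habitat, so the
#' effective density is `targets_per_cell / cover`: 200, 286 and 500 per
#' km2 of habitat for large-, medium- and small-river cells at the standard
#' 20 targets per cell.
#'
#' @param plan A [deployment_plan()].
#' @param grid A `tsetse_grid`.
#' @return Numeric vector, one value per treated cell of the plan.
#' @export
target_density_per_habitat <- function(plan, grid) {
  cover <- grid_cover(grid)[plan$cells]
  if (any(cover <= 0)) stop("treated cell with zero habitat cover",
                            call. = FALSE)
  plan$targets_per_cell / cover
}

#' Days since the last (re)deployment under a plan
#'
#' Deployment happens on `start_day` and again at the start of each
#' `refresh_period`-day cycle ("the beginning of the 184th day"), when the
#' remaining old targets are discarded and a full fresh set is deployed.
#'
#' @param plan A [deployment_plan()].
#' @param day Current day.
#' @return Integer days since deployment (0 on a deployment day), or `NA`
#'   if the plan is not active on `day`.
#' @export
days_since_deployment <- function(plan, day) {
  if (day < plan$start_day || day > plan$end_day) return(NA_integer_)
  as.integer((day - plan$start_day) %% plan$refresh_period)
}

#' One day of target-induced mortality
#'
#' Each adult cohort in each treated cell is multiplied by `1 - q`, with
#' `q = min(1, rate(age, sex) * target_density_per_habitat * efficacy)`:
#' kill rates compose linearly in target density (rates are defined per
#' target at unit density), capped at 1.  Untreated cells and pupae are
#' unaffected.
#'
#' @param state A `tsetse_state`.
#' @param grid A `tsetse_grid`.
#' @param plan A [deployment_plan()]; if `NULL` or inactive on
#'   `state$day` the state is returned unchanged.
#' @param day Day used for the plan's activity and degradation; defaults
#'   to `state$day`.
#' @return The state after control mortality.
#' @export
control_step <- function(state, grid, plan, day = state$day) {
  if (is.null(plan)) return(state)
  dsd <- days_since_deployment(plan, day)
  if (is.na(dsd)) return(state)
  eff <- degraded_efficacy(dsd, plan$degradation_rate)
  dens <- target_density_per_habitat(plan, grid)
  qf <- pmin(1, outer(dens * eff, plan$schedule$rate_female))
  qm <- pmin(1, outer(dens * eff, plan$schedule$rate_male))
  tc <- plan$cells
  state$F[tc, ] <- state$F[tc, , drop = FALSE] * (1 - qf)
  state$M[tc, ] <- state$M[tc, , drop = FALSE] * (1 - qm)
  state
}
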