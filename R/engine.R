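#' Create a population state
#'
#' The state holds continuous-valued counts of adult females and males by
#' daily age class and cell, and of pupae by age and natal cell.  `"naive"`
#' seeding puts each cell at its class's naive capacity (habitat cover times
#' SNCC) with the stable age structure of the homogeneous best-habitat
#' model; `"empty"` starts from zero.
#'
#' @param grid A `tsetse_grid`.
#' @param config A `tsetse_config`.
#' @param fill `"naive"`, `"equilibrium"` or `"empty"`.  `"equilibrium"`
#'   seeds each cell at its habitat class's full lifetable equilibrium
#'   (see [class_equilibrium()]), which is the exact fixed point of the
#'   no-movement model.
#' @param day Starting day index.
#' @return Object of class `tsetse_state`.
#' @export
population_state <- function(grid, config = standard_config(),
                             fill = c("naive", "equilibrium", "empty"),
                             day = 0) {
  fill <- match.arg(fill)
  config <- prepare_config(config)
  dem <- config$demography
  der <- config$derived
  n <- grid$nrow * grid$ncol
  A <- dem$max_adult_age
  PD <- dem$pupal_duration
  F <- matrix(0, n, A)
  M <- matrix(0, n, A)
  P <- matrix(0, n, PD)
  cover <- grid_cover(grid)
  if (fill == "naive") {
    st <- der$stationary
    F <- (cover * dem$sncc_female) %o% st$age_profile_female
    M <- (cover * dem$sncc_male) %o% st$age_profile_male
    P <- (cover * der$sncc_pupal_density) %o% st$pupal_profile
  } else if (fill == "equilibrium") {
    cls <- as.vector(grid$class)
    a <- seq_len(A)
    j <- seq_len(PD)
    norm <- function(x) x / sum(x)
    for (ic in seq_len(nrow(grid$habitat))) {
      sel <- cls == ic
      if (!any(sel)) next
      eq <- class_equilibrium(config, grid$habitat$mortality_factor[ic])
      if (eq$females <= 0) next
      pf <- norm((1 - eq$rates$mf)^(a - 1))
      pm <- norm((1 - eq$rates$mm)^(a - 1))
      pp <- norm((1 - eq$rates$mp)^(j - 1))
      F[sel, ] <- (cover[sel] * eq$females) %o% pf
      M[sel, ] <- (cover[sel] * eq$males) %o% pm
      P[sel, ] <- (cover[sel] * eq$pupae) %o% pp
    }
  }
  structure(list(F = F, M = M, P = P, mature = NULL, day = day),
            class = "tsetse_state")
}

#' @export
print.tsetse_state <- function(x, ...) {
  cat("<tsetse_state> day ", x$day, ": ",
      format(round(sum(x$F))), " females, ", format(round(sum(x$M))),
      " males, ", format(round(sum(x$P))), " pupae in ", nrow(x$F),
      " cells\n", sep = "")
  invisible(x)
}

#' Per-cell pooled adult counts of a state
#'
#' @param state A `tsetse_state`.
#' @return Numeric vector, males plus females per cell.
#' @export
baseline_population <- function(state) {
  rowSums(state$F) + rowSums(state$M)
}

#' Precomputed per-landscape simulation operators
#'
#' Builds everything the daily loop needs from the grid and configuration:
#' the sparse movement operator, the per-age evacuation probabilities, the
#' per-cell cover and mortality-factor vectors and the fecundity schedule.
#'
#' @param grid A `tsetse_grid`.
#' @param config A prepared `tsetse_config`.
#' @return A list used by the step functions and [run_day()].
#' @export
simulation_operators <- function(grid, config) {
  config <- prepare_config(config)
  A <- movement_matrix(grid, config)
  list(
    Ai = A@i, Ap = A@p, Ax = A@x,
    cover = grid_cover(grid),
    mfac = grid_mortality_factor(grid),
    evac_female = config$derived$evac_female,
    evac_male = config$derived$evac_male,
    fecundity = config$derived$fecundity,
    config = config
  )
}

#' Age every compartment by one day
#'
#' Counts move up one daily age class; the age-1 classes empty; adults
#' beyond the last age class are removed; pupae completing development are
#' set aside in `state$mature` for emergence at the end of the day.
#'
#' @param state A `tsetse_state`.
#' @return The aged state.
#' @export
age_step <- function(state) {
  state$F <- cpp_age_adults(state$F)
  state$M <- cpp_age_adults(state$M)
  ap <- cpp_age_pupae(state$P)
  state$P <- ap$pupae
  state$mature <- (state$mature %||% 0) + ap$mature
  state$day <- state$day + 1
  state
}

#' One day of density-dependent natural mortality
#'
#' Each cohort is multiplied by `1 - factor(cell) * m_d`, where `m_d` is the
#' density-dependent daily death rate (see
#' [density_dependent_death_rate()]) and `factor` the habitat class's
#' mortality multiplier; survival is clamped to \[0, 1\].  Adult rates use
#' the cell's total adults per km2 of habitat, pupal rates its total pupae
#' (including the day's maturing pupae) per km2 of habitat.
#'
#' @param state A `tsetse_state`.
#' @param grid A `tsetse_grid`.
#' @param config A `tsetse_config`.
#' @param ops Optional precomputed [simulation_operators()].
#' @return The state after natural mortality.
#' @export
natural_mortality_step <- function(state, grid, config = standard_config(),
                                   ops = NULL) {
  if (is.null(ops)) {
    config <- prepare_config(config)
    ops <- list(cover = grid_cover(grid),
                mfac = grid_mortality_factor(grid), config = config)
  }
  cfg <- ops$config
  der <- cfg$derived
  mature <- state$mature %||% numeric(nrow(state$P))
  res <- cpp_mortality(state$F, state$M, state$P, mature,
                       ops$cover, ops$mfac,
                       der$ms_female, der$ms_male,
                       cfg$demography$pupal_mortality_sncc,
                       cfg$demography$k,
                       der$sncc_adult_density, der$sncc_pupal_density)
  state$F <- res$F
  state$M <- res$M
  state$P <- res$P
  if (!is.null(state$mature)) state$mature <- res$mature
  state
}

#' One day of lattice movement
#'
#' All adults at a cell centre start moving equally in the four orthogonal
#' directions; a fraction `p_evac(sex, age) / 4 * directional_factor`
#' transfers to each neighbouring cell centre and the rest return to the
#' origin centre.  Pupae do not move.  Movement conserves each sex-age
#' cohort exactly; map edges reflect.
#'
#' @inheritParams natural_mortality_step
#' @return The state after movement.
#' @export
movement_step <- function(state, grid, config = standard_config(),
                          ops = NULL) {
  if (is.null(ops)) ops <- simulation_operators(grid, config)
  if (!isTRUE(ops$config$mobility$enabled)) return(state)
  state$F <- cpp_move(state$F, ops$Ai, ops$Ap, ops$Ax, ops$evac_female)
  state$M <- cpp_move(state$M, ops$Ai, ops$Ap, ops$Ax, ops$evac_male)
  state
}

#' One day of larviposition
#'
#' Each female on the larviposition schedule deposits one larva, which
#' pupates immediately in its natal cell (egg and larval mortality are
#' zero).  Under the default smeared schedule every female at or beyond the
#' age of first larviposition contributes at rate `1 / interlarval_period`
#' per day; under the synchronized schedule females whose age falls exactly
#' on the schedule each deposit one larva.
#'
#' @param state A `tsetse_state`.
#' @param config A `tsetse_config`.
#' @return The state with the day's crop of age-1 pupae added.
#' @export
larviposition_step <- function(state, config = standard_config()) {
  config <- prepare_config(config)
  L <- as.vector(state$F %*% config$derived$fecundity)
  state$P[, 1] <- state$P[, 1] + L
  attr(state, "larvae") <- sum(L)
  state
}

#' Emergence of mature pupae
#'
#' Pupae that completed development become age-1 adults of each sex in
#' equal numbers, in their natal cell.
#'
#' @param state A `tsetse_state`.
#' @param config A `tsetse_config`.
#' @return The state after emergence.
#' @export
emergence_step <- function(state, config = standard_config()) {
  mature <- state$mature
  if (is.null(mature)) {
    pd <- ncol(state$P)
    mature <- state$P[, pd]
    state$P[, pd] <- 0
  }
  state$F[, 1] <- state$F[, 1] + 0.5 * mature
  state$M[, 1] <- state$M[, 1] + 0.5 * mature
  state$mature <- NULL
  state
}

#' Run one simulated day
#'
#' Executes the daily sequence: advance the date and age every compartment;
#' natural mortality; movement; control mortality from targets; the day's
#' larviposition; emergence of mature pupae.
#'
#' @param state A `tsetse_state`.
#' @param grid A `tsetse_grid`.
#' @param config A `tsetse_config`.
#' @param plan A [deployment_plan()] or `NULL` for no control.
#' @param ops Optional precomputed [simulation_operators()].
#' @return The state at the end of the day, with attributes `larvae`
#'   (pupae deposited) and `killed_female`/`killed_male` (flies killed by
#'   targets that day).
#' @export
run_day <- function(state, grid, config = standard_config(), plan = NULL,
                    ops = NULL) {
  if (is.null(ops)) ops <- simulation_operators(grid, config)
  state <- age_step(state)
  state <- natural_mortality_step(state, grid, ops = ops)
  state <- movement_step(state, grid, ops = ops)
  f_pre <- sum(state$F)
  m_pre <- sum(state$M)
  state <- control_step(state, grid, plan)
  kf <- f_pre - sum(state$F)
  km <- m_pre - sum(state$M)
  state <- larviposition_step(state, ops$config)
  larvae <- attr(state, "larvae")
  state <- emergence_step(state, ops$config)
  attr(state, "larvae") <- larvae
  attr(state, "killed_female") <- kf
  attr(state, "killed_male") <- km
  attr(state, "females_pre_control") <- f_pre
  attr(state, "males_pre_control") <- m_pre
  state
}

#' Burn in to the stable uncontrolled distribution
#'
#' Seeds flies into all cells and iterates the daily cycle with no control
#' until the distribution stabilises, following the combined effects of
#' mobility, natural mortality and habitat abundance.  Iteration stops when
#' the maximum relative day-to-day change of any cell's pooled adult count
#' falls below `tol` (cells below `floor` flies are treated as empty for
#' the purpose of the criterion), or after `max_iter` days.
#'
#' @param grid A `tsetse_grid`.
#' @param config A `tsetse_config`.
#' @param max_iter Maximum iterations (standard 10000).
#' @param tol Convergence tolerance on the per-cell daily relative change.
#' @param floor Absolute count below which a cell is considered empty.
#' @param state Optional starting state; default naive seeding.
#' @return The converged `tsetse_state`, with attributes `iterations` and
#'   `max_rel_change`.  Warns (with a growth-rate diagnostic) if the
#'   tolerance was not reached within `max_iter`.
#' @export
burn_in <- function(grid, config = standard_config(),
                    max_iter = config$burn_in$max_iter,
                    tol = config$burn_in$tol, floor = 1e-6,
                    state = NULL) {
  config <- prepare_config(config)
  ops <- simulation_operators(grid, config)
  if (is.null(state)) state <- population_state(grid, config, "naive")
  rel <- Inf
  it <- 0L
  chunk <- 200L
  while (it < max_iter) {
    nd <- min(chunk, max_iter - it)
    res <- run_chunk_cpp(state, ops, eff_by_day = rep(-1, nd),
                         treated = integer(0), tdens = numeric(0),
                         rate_f = numeric(0), rate_m = numeric(0),
                         ndays = nd, record = FALSE,
                         rec_cells = integer(0),
                         track_change = TRUE, change_floor = floor)
    state$F <- res$F
    state$M <- res$M
    state$P <- res$P
    state$day <- state$day + nd
    it <- it + nd
    rel <- tail(res$rel_change, 1)
    if (any(res$rel_change < tol)) break
  }
  if (rel >= tol) {
    tots <- sum(state$F) + sum(state$M)
    warning("burn-in did not converge in ", max_iter,
            " iterations: max relative daily change ", signif(rel, 3),
            " (total adult population ", signif(tots, 6), ")",
            call. = FALSE)
  }
  attr(state, "iterations") <- it
  attr(state, "max_rel_change") <- rel
  state
}

#' Low-level wrapper around the fused C++ daily loop
#' @noRd
run_chunk_cpp <- function(state, ops, eff_by_day, treated, tdens,
                          rate_f, rate_m, ndays, record, rec_cells,
                          old_age = 40, mobile_age = 10,
                          track_change = FALSE, change_floor = 1e-6) {
  cfg <- ops$config
  der <- cfg$derived
  cpp_run_chunk(state$F, state$M, state$P,
                ops$cover, ops$mfac,
                der$ms_female, der$ms_male,
                cfg$demography$pupal_mortality_sncc,
                cfg$demography$k,
                der$sncc_adult_density, der$sncc_pupal_density,
                ops$Ai, ops$Ap, ops$Ax,
                ops$evac_female, ops$evac_male,
                isTRUE(cfg$mobility$enabled),
                ops$fecundity,
                as.integer(treated) - 1L, tdens, rate_f, rate_m,
                eff_by_day, as.integer(ndays),
                record, as.integer(rec_cells) - 1L,
                as.integer(old_age), as.integer(mobile_age),
                track_change, change_floor)
}

#' Run a simulation and record daily outputs
#'
#' Iterates [run_day()] for `days` days from `state`, applying whichever of
#' `plans` is active each day, and records daily totals, kill fractions,
#' pupal production, global age distributions and per-cell series.
#'
#' @param state Starting `tsetse_state` (typically from [burn_in()]).
#' @param grid A `tsetse_grid`.
#' @param config A `tsetse_config`.
#' @param plans A single [deployment_plan()], a list of plans (at most one
#'   may be active on any day), or `NULL`.
#' @param days Number of days to simulate.
#' @param record_cells Cell ids for the per-cell series, `"all"`, or
#'   `NULL` to skip per-cell recording.
#' @return Object of class `tsetse_run`; see [tidy.tsetse_run()].
#' @export
run_simulation <- function(state, grid, config = standard_config(),
                           plans = NULL, days = 366,
                           record_cells = "all") {
  config <- prepare_config(config)
  ops <- simulation_operators(grid, config)
  if (inherits(plans, "deployment_plan")) plans <- list(plans)
  for (p in plans %||% list()) {
    stopifnot(inherits(p, "deployment_plan"))
    if (length(p$schedule$rate_female) != config$demography$max_adult_age) {
      stop("plan kill schedule has ", length(p$schedule$rate_female),
           " age classes but the configuration has ",
           config$demography$max_adult_age, call. = FALSE)
    }
  }
  n <- grid$nrow * grid$ncol
  if (identical(record_cells, "all")) record_cells <- seq_len(n)
  A <- config$demography$max_adult_age
  old <- config$metrics$old_age
  mob <- config$metrics$mobile_age
  nd <- as.integer(days)
  day_v <- integer(nd)
  sc <- matrix(NA_real_, nd, 7,
               dimnames = list(NULL, c("females", "males", "pupae",
                                       "pupae_deposited", "kill_frac_female",
                                       "kill_frac_male", "phase")))
  fage <- matrix(0, A, nd)
  mage <- matrix(0, A, nd)
  nr <- length(record_cells)
  cell_adults <- if (nr) matrix(0, nr, nd)
  cell_females <- if (nr) matrix(0, nr, nd)
  cell_females_old <- if (nr) matrix(0, nr, nd)
  cell_adults_mobile <- if (nr) matrix(0, nr, nd)

  # which plan (if any) is active on each simulated day
  abs_days <- state$day + seq_len(nd)
  plan_id <- integer(nd)
  for (ip in seq_along(plans %||% list())) {
    p <- plans[[ip]]
    on <- abs_days >= p$start_day & abs_days <= p$end_day
    if (any(plan_id[on] != 0)) {
      stop("overlapping deployment plans", call. = FALSE)
    }
    plan_id[on] <- ip
  }
  # run in maximal chunks with a constant active plan
  runs <- rle(plan_id)
  t0 <- 0L
  for (seg in seq_along(runs$lengths)) {
    len <- runs$lengths[seg]
    ip <- runs$values[seg]
    idx <- t0 + seq_len(len)
    if (ip == 0) {
      eff <- rep(-1, len)
      treated <- integer(0)
      tdens <- numeric(0)
      rate_f <- rate_m <- numeric(0)
    } else {
      p <- plans[[ip]]
      dsd <- vapply(abs_days[idx], function(d) days_since_deployment(p, d),
                    integer(1))
      eff <- degraded_efficacy(dsd, p$degradation_rate)
      treated <- p$cells
      tdens <- target_density_per_habitat(p, grid)
      rate_f <- p$schedule$rate_female
      rate_m <- p$schedule$rate_male
    }
    res <- run_chunk_cpp(state, ops, eff_by_day = eff, treated = treated,
                         tdens = tdens, rate_f = rate_f, rate_m = rate_m,
                         ndays = len, record = TRUE, rec_cells = record_cells,
                         old_age = old, mobile_age = mob)
    state$F <- res$F
    state$M <- res$M
    state$P <- res$P
    state$day <- state$day + len
    day_v[idx] <- abs_days[idx]
    sc[idx, "females"] <- res$females
    sc[idx, "males"] <- res$males
    sc[idx, "pupae"] <- res$pupae
    sc[idx, "pupae_deposited"] <- res$larvae
    sc[idx, "kill_frac_female"] <-
      ifelse(res$fpre > 0, res$killed_f / res$fpre, NA_real_)
    sc[idx, "kill_frac_male"] <-
      ifelse(res$mpre > 0, res$killed_m / res$mpre, NA_real_)
    sc[idx, "phase"] <- as.numeric(ip != 0)
    fage[, idx] <- res$fage
    mage[, idx] <- res$mage
    if (nr) {
      cell_adults[, idx] <- res$cell_adults
      cell_females[, idx] <- res$cell_females
      cell_females_old[, idx] <- res$cell_females_old
      cell_adults_mobile[, idx] <- res$cell_adults_mobile
    }
    t0 <- t0 + len
  }
  records <- tibble::tibble(
    day = day_v,
    females = sc[, "females"], males = sc[, "males"],
    adults = sc[, "females"] + sc[, "males"],
    pupae = sc[, "pupae"], pupae_deposited = sc[, "pupae_deposited"],
    kill_frac_female = sc[, "kill_frac_female"],
    kill_frac_male = sc[, "kill_frac_male"],
    control_active = sc[, "phase"] > 0
  )
  structure(list(records = records, days = day_v,
                 cells = record_cells,
                 cell_adults = cell_adults, cell_females = cell_females,
                 cell_females_old = cell_females_old,
                 cell_adults_mobile = cell_adults_mobile,
                 female_by_age = fage, male_by_age = mage,
                 final_state = state, grid = grid, config = config),
            class = "tsetse_run")
}

#' @export
print.tsetse_run <- function(x, ...) {
  cat("<tsetse_run> days ", min(x$days), "-", max(x$days), " (",
      length(x$days), " days), ", length(x$cells),
      " recorded cells\n", sep = "")
  invisible(x)
}

#' Run a multi-phase control scenario
#'
#' Executes successive deployment phases continuously from a starting
#' state, carrying the population over between phases.  Phases must be
#' ordered and non-overlapping in time; days between phases are simulated
#' without control.
#'
#' @param grid A `tsetse_grid`.
#' @param config A `tsetse_config`.
#' @param phases List of [deployment_plan()]s ordered by `start_day`.
#' @param state Starting state; if `NULL`, [burn_in()] is run first.
#' @param record_cells As in [run_simulation()].
#' @return Object of class `tsetse_scenario`: list with `baseline` (per-cell
#'   pre-control adults), `phases` (named list of `tsetse_run`), `grid`,
#'   `config`.
#' @export
run_scenario <- function(grid, config = standard_config(), phases,
                         state = NULL, record_cells = "all") {
  config <- prepare_config(config)
  stopifnot(length(phases) >= 1)
  ord <- order(vapply(phases, `[[`, numeric(1), "start_day"))
  phases <- phases[ord]
  for (i in seq_along(phases)[-1]) {
    if (phases[[i]]$start_day <= phases[[i - 1]]$end_day) {
      stop("deployment phases overlap in time", call. = FALSE)
    }
  }
  if (is.null(state)) state <- burn_in(grid, config)
  baseline <- baseline_population(state)
  state$day <- phases[[1]]$start_day - 1
  runs <- list()
  for (i in seq_along(phases)) {
    p <- phases[[i]]
    gap <- p$start_day - 1 - state$day
    if (gap > 0) {
      r0 <- run_simulation(state, grid, config, plans = NULL, days = gap,
                           record_cells = record_cells)
      state <- r0$final_state
    }
    r <- run_simulation(state, grid, config, plans = p,
                        days = p$end_day - p$start_day + 1,
                        record_cells = record_cells)
    state <- r$final_state
    runs[[p$name %||% paste0("phase", i)]] <- r
  }
  structure(list(baseline = baseline, phases = runs, grid = grid,
                 config = config, final_state = state),
            class = "tsetse_scenario")
}

#' @export
print.tsetse_scenario <- function(x, ...) {
  cat("<tsetse_scenario> ", length(x$phases), " phases: ",
      paste(names(x$phases), collapse = ", "), "\n", sep = "")
  invisible(x)
}
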