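#' Standard simulation configuration
#'
#' Returns the full parameter set of the model with its standard values:
#' carrying capacities at the standard natural carrying capacity (SNCC) of
#' 5000 adult females and 2500 adult males per km2 of best habitat,
#' density-dependence constant k = 0.1, a 10-day interlarval (reproductive)
#' cycle with first larviposition at adult age 16 days, a 30-day pupal
#' period, 100 daily adult age classes, pupal daily mortality 0.005 at SNCC,
#' zero egg/larval mortality, and the mobility and control standards
#' described in [mobility_params()] and [deployment_plan()].
#'
#' The two adult natural death rates (one per sex, flat across ages) are not
#' free inputs: they are solved by [goal_seek_natural_mortality()] so that
#' the uncontrolled, no-net-movement population in best habitat is
#' stationary at SNCC.  [prepare_config()] fills them in, together with the
#' SNCC pupal density and the calibrated evacuation tables.
#'
#' @param demography,mobility Optional lists overriding individual fields.
#' @return A list of class `tsetse_config`.
#' @examples
#' cfg <- standard_config()
#' cfg$demography$interlarval_period
#' @export
standard_config <- function(demography = list(), mobility = list()) {
  dem <- list(
    sncc_female = 5000, sncc_male = 2500,
    k = 0.1,
    interlarval_period = 10,
    age_first_larviposition = 16,
    pupal_duration = 30,
    max_adult_age = 100,
    pupal_mortality_sncc = 0.005,
    immature_mortality = 0,
    larviposition = "smeared",  # or "synchronized"
    ms_female = NULL, ms_male = NULL, sncc_pupal_density = NULL
  )
  mob <- list(
    displacement_age1 = 0.2,    # km/day, newly emerged females
    displacement_max = 0.4,     # km/day, females >= mature_age days old
    mature_age = 10,
    male_multiplier = 0.5,
    interfluve_entry_factor = 0.01,
    calibration_horizon = 30,   # days
    enabled = TRUE
  )
  dem[names(demography)] <- demography
  mob[names(mobility)] <- mobility
  cfg <- list(
    demography = dem,
    mobility = mob,
    burn_in = list(max_iter = 10000, tol = 1e-6),
    metrics = list(old_age = 40, mobile_age = 10),
    derived = NULL
  )
  class(cfg) <- "tsetse_config"
  validate_config(cfg)
  cfg
}

#' @noRd
validate_config <- function(cfg) {
  d <- cfg$demography
  stopifnot(d$sncc_female > 0, d$sncc_male > 0,
            d$k >= 0, d$k <= 1,
            d$interlarval_period >= 1,
            d$age_first_larviposition >= 1,
            d$pupal_duration >= 1,
            d$max_adult_age > d$age_first_larviposition,
            d$pupal_mortality_sncc >= 0, d$pupal_mortality_sncc < 1,
            d$larviposition %in% c("smeared", "synchronized"))
  m <- cfg$mobility
  stopifnot(m$displacement_age1 >= 0, m$displacement_max >= 0,
            m$male_multiplier >= 0, m$male_multiplier <= 1,
            m$interfluve_entry_factor >= 0, m$interfluve_entry_factor <= 1,
            m$calibration_horizon >= 1)
  invisible(cfg)
}

#' @export
print.tsetse_config <- function(x, ...) {
  cat("<tsetse_config>", if (is.null(x$derived)) "(unprepared)" else
    "(prepared)", "\n")
  cat("  SNCC:", x$demography$sncc_female, "F +", x$demography$sncc_male,
      "M per km2 habitat; k =", x$demography$k, "\n")
  if (!is.null(x$derived)) {
    cat("  solved ms: female", signif(x$derived$ms_female, 6),
        " male", signif(x$derived$ms_male, 6), "\n")
    cat("  SNCC pupal density:", signif(x$derived$sncc_pupal_density, 6),
        "per km2 habitat\n")
  }
  invisible(x)
}

#' Daily fecundity schedule (larvae per female per day, by adult age)
#' @noRd
fecundity_vector <- function(dem) {
  a <- seq_len(dem$max_adult_age)
  f <- numeric(dem$max_adult_age)
  if (dem$larviposition == "smeared") {
    f[a >= dem$age_first_larviposition] <- 1 / dem$interlarval_period
  } else {
    due <- a >= dem$age_first_larviposition &
      (a - dem$age_first_larviposition) %% dem$interlarval_period == 0
    f[due] <- 1
  }
  f
}

#' Density-dependent natural death rate
#'
#' The daily natural death rate at density `d` is
#' `ms * ((1 - k) + k * d / s)`: at the SNCC density (`d = s`) it equals the
#' habitat's standard rate `ms`; as density falls to zero it declines by a
#' factor `1 - k` (0.9 at the standard k = 0.1).  Adult rates use the total
#' of males plus females per km2 of habitat; pupal rates use the total
#' pupae of both sexes per km2 of habitat.
#'
#' @param ms Daily death rate at SNCC for the sex/age/habitat in question.
#' @param d Current density per km2 of habitat (>= 0).
#' @param s Density at SNCC (> 0).
#' @param k Density-dependence constant in \[0, 1\].
#' @return Daily death rate(s), same length as the longest argument.
#' @examples
#' density_dependent_death_rate(0.02, d = 0, s = 7500, k = 0.1)  # 0.9 * ms
#' @export
density_dependent_death_rate <- function(ms, d, s, k = 0.1) {
  if (any(d < 0)) stop("density d must be >= 0", call. = FALSE)
  if (any(s <= 0)) stop("SNCC density s must be > 0", call. = FALSE)
  if (any(k < 0 | k > 1)) stop("k must lie in [0, 1]", call. = FALSE)
  ms * ((1 - k) + k * d / s)
}

#' Long-run daily growth rate of the female line at fixed death rates
#'
#' Dominant-eigenvalue growth rate (per day, log scale) of the female
#' renewal process with flat adult mortality `mf`, pupal mortality `mp`
#' and the configured fecundity schedule, all densities held fixed.
#' @noRd
female_growth_rate <- function(mf, mp, dem) {
  fec <- fecundity_vector(dem)
  a <- seq_len(dem$max_adult_age)
  lf <- (1 - mf)^(a - 1)
  sp <- (1 - mp)^dem$pupal_duration
  net <- function(r) {
    sum(0.5 * fec * sp * lf * exp(-r * (a + dem$pupal_duration))) - 1
  }
  if (net(0) == 0) return(0)
  uniroot(net, lower = -0.5, upper = 0.5, tol = 1e-14)$root
}

#' Solve natural adult mortality for stationarity at SNCC
#'
#' Finds the flat daily natural death rates of adult females and males such
#' that the uncontrolled, no-net-movement population in homogeneous best
#' habitat is stationary at the standard natural carrying capacity (5000
#' females and 2500 males per km2 of habitat).  The female rate is found by
#' a bracketing root search on the long-run daily growth rate of the female
#' line (|growth| < 1e-8 per day at the solution); the male rate is then
#' solved so that the male standing population is the required fraction of
#' the female one given the equal recruitment of the sexes.  Both solved
#' rates are corrected for the engine's within-day accounting (density is
#' read after aging, before emergence), so that the simulated fixed point
#' sits at SNCC, not merely the continuous-time one.
#'
#' The SNCC pupal density - the reference density `s` of the pupal
#' density-dependence term - is not a free input: it is the equilibrium
#' standing pupal density implied by the solved lifetable, so that pupal
#' death rates equal their SNCC value exactly at equilibrium.
#'
#' @param config A `tsetse_config`.
#' @return A list: `ms_female`, `ms_male` (daily rates at SNCC in best
#'   habitat), `sncc_pupal_density` (pupae per km2 habitat),
#'   `growth_residual` (per day), and the equilibrium age profiles.
#' @export
goal_seek_natural_mortality <- function(config) {
  dem <- config$demography
  a <- seq_len(dem$max_adult_age)
  mp <- dem$pupal_mortality_sncc
  g <- function(mf) female_growth_rate(mf, mp, dem)
  if (g(1e-9) < 0 || g(0.2) > 0) {
    stop("no stationary adult death rate in [0, 0.2]/day: ",
         "inconsistent demographic parameter set", call. = FALSE)
  }
  mf <- uniroot(g, lower = 1e-9, upper = 0.2, tol = 1e-13)$root
  lf <- 1 - mf

  # male rate: equal daily recruitment of the sexes, so standing totals are
  # proportional to the sums of the survivorship series
  S <- function(l, n) if (l == 1) n else (1 - l^n) / (1 - l)
  target <- dem$sncc_male / dem$sncc_female * S(lf, dem$max_adult_age)
  h <- function(mm) S(1 - mm, dem$max_adult_age) - target
  if (h(mf) < 0) {
    stop("male SNCC exceeds female SNCC; cannot solve male death rate",
         call. = FALSE)
  }
  mm <- uniroot(h, lower = mf, upper = 0.999999, tol = 1e-13)$root
  lm <- 1 - mm

  # engine reads adult density after aging (ages 2..A of yesterday's
  # profile) and before emergence; correct ms so the applied rate at the
  # SNCC fixed point equals the solved stationary rate
  snap <- (S(lf, dem$max_adult_age - 1) + S(lm, dem$max_adult_age - 1)) /
    (S(lf, dem$max_adult_age) + S(lm, dem$max_adult_age))
  dd_at_eq <- (1 - dem$k) + dem$k * snap
  ms_female <- mf / dd_at_eq
  ms_male <- mm / dd_at_eq

  fec <- fecundity_vector(dem)
  n1 <- dem$sncc_female / S(lf, dem$max_adult_age)  # age-1 females per km2
  larvae <- n1 * sum(fec * lf^(a - 1))              # larvae per day per km2
  sncc_pupal_density <- larvae * S(1 - mp, dem$pupal_duration)

  list(ms_female = ms_female, ms_male = ms_male,
       sncc_pupal_density = sncc_pupal_density,
       growth_residual = g(mf),
       stationary = list(
         mf = mf, mm = mm, mp = mp,
         age_profile_female = lf^(a - 1) / S(lf, dem$max_adult_age),
         age_profile_male = lm^(a - 1) / S(lm, dem$max_adult_age),
         pupal_profile = (1 - mp)^(seq_len(dem$pupal_duration) - 1) /
           S(1 - mp, dem$pupal_duration),
         larvae_per_day_km2 = larvae, recruits_per_day_km2 = n1
       ))
}

#' Prepare a configuration for simulation
#'
#' Fills in the derived quantities a run needs: the goal-sought natural
#' death rates, the SNCC pupal density, the fecundity schedule and the
#' calibrated per-age evacuation probabilities.  Idempotent.
#'
#' @param config A `tsetse_config`.
#' @return The configuration with `$derived` populated.
#' @export
prepare_config <- function(config) {
  validate_config(config)
  if (!is.null(config$derived)) return(config)
  gs <- goal_seek_natural_mortality(config)
  dem <- config$demography
  der <- list(
    ms_female = dem$ms_female %||% gs$ms_female,
    ms_male = dem$ms_male %||% gs$ms_male,
    sncc_pupal_density = dem$sncc_pupal_density %||% gs$sncc_pupal_density,
    sncc_adult_density = dem$sncc_female + dem$sncc_male,
    fecundity = fecundity_vector(dem),
    stationary = gs$stationary,
    evac_female = NULL, evac_male = NULL
  )
  et <- evacuation_table(config)
  der$evac_female <- et$female
  der$evac_male <- et$male
  config$derived <- der
  config
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Equilibrium population of one habitat class
#'
#' Solves the no-movement, no-control equilibrium of the full lifetable when
#' every natural death rate at SNCC is multiplied by the class's mortality
#' factor, using the same density-dependence and within-day accounting as
#' the simulation engine.  For the best habitat (factor 1) this returns the
#' SNCC itself; for sufficiently degraded habitat the lifetable is
#' sub-replacement even at zero density and the equilibrium is extinction.
#'
#' @param config A prepared or unprepared `tsetse_config`.
#' @param mortality_factor Multiplier (>= 1) on all natural death rates.
#' @return List with per-km2-habitat densities `females`, `males` (standing,
#'   end-of-day), `pupae`, and the equilibrium rates.
#' @export
class_equilibrium <- function(config, mortality_factor = 1) {
  config <- prepare_config(config)
  dem <- config$demography
  der <- config$derived
  phi <- mortality_factor
  A <- dem$max_adult_age
  PD <- dem$pupal_duration
  k <- dem$k
  fec <- der$fecundity
  a <- seq_len(A)
  S <- function(l, n) if (l == 1) n else (1 - l^n) / (1 - l)
  empty <- list(females = 0, males = 0, pupae = 0, rates = NULL)

  # extinction check at zero density (most favourable rates)
  mf0 <- phi * der$ms_female * (1 - k)
  mp0 <- phi * dem$pupal_mortality_sncc * (1 - k)
  if (mf0 >= 1) return(empty)
  R0 <- 0.5 * (1 - mp0)^PD * sum(fec * (1 - mf0)^(a - 1))
  if (R0 <= 1) return(empty)

  s_a <- der$sncc_adult_density
  s_p <- der$sncc_pupal_density
  resid <- function(mf) {
    lf <- 1 - mf
    sfec <- sum(fec * lf^(a - 1))
    surv_needed <- 1 / (0.5 * sfec)       # required (1-mp)^PD
    if (surv_needed >= 1) return(NA_real_)
    mpx <- 1 - surv_needed^(1 / PD)
    rho_a <- (mf / (phi * der$ms_female) - (1 - k)) / k
    rho_p <- (mpx / (phi * dem$pupal_mortality_sncc) - (1 - k)) / k
    mmx <- phi * der$ms_male * ((1 - k) + k * rho_a)
    lm <- 1 - mmx
    d_ad_snap <- S(lf, A - 1) + S(lm, A - 1)          # per recruit
    d_pu_snap <- sfec * S(1 - mpx, PD)                # per recruit
    d_pu_snap / d_ad_snap - (rho_p * s_p) / (rho_a * s_a)
  }
  # scan for a sign change (the residual is undefined once the adult rate
  # is too high for the lifetable to replace itself at any pupal rate)
  lo <- mf0 * (1 + 1e-9)
  hi <- min(0.999, phi * der$ms_female * ((1 - k) + 4 * k))
  mf_grid <- seq(lo, hi, length.out = 257)
  r_grid <- vapply(mf_grid, resid, numeric(1))
  ok <- which(is.finite(r_grid))
  if (!length(ok)) return(empty)
  sgn <- sign(r_grid[ok])
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flip)) return(empty)
  i1 <- ok[flip[1]]
  i2 <- ok[flip[1] + 1]
  mf <- uniroot(resid, lower = mf_grid[i1], upper = mf_grid[i2],
                tol = 1e-13)$root
  lf <- 1 - mf
  sfec <- sum(fec * lf^(a - 1))
  mp <- 1 - (1 / (0.5 * sfec))^(1 / PD)
  rho_a <- (mf / (phi * der$ms_female) - (1 - k)) / k
  mm <- phi * der$ms_male * ((1 - k) + k * rho_a)
  lm <- 1 - mm
  # scale from the snapshot adult density
  n1 <- rho_a * s_a / (S(lf, A - 1) + S(lm, A - 1))
  list(females = n1 * S(lf, A), males = n1 * S(lm, A),
       pupae = n1 * sfec * S(1 - mp, PD),
       rates = list(mf = mf, mm = mm, mp = mp))
}

#' Natural carrying capacity of grid cells
#'
#' Per-cell equilibrium adult numbers with no net movement and no control:
#' the class equilibrium density per km2 of habitat (see
#' [class_equilibrium()]) scaled by the cell's habitat cover.  For
#' large-river cells under the standard parameterization this is 500 females
#' and 250 males per cell; interfluve cells are sub-replacement and carry 0.
#'
#' @param grid A `tsetse_grid`.
#' @param config A `tsetse_config`.
#' @param cells Optional cell ids; default all cells.
#' @return Tibble: cell, row, col, class, males, females (per cell).
#' @export
carrying_capacity <- function(grid, config = standard_config(),
                              cells = NULL) {
  config <- prepare_config(config)
  if (is.null(cells)) cells <- seq_len(grid$nrow * grid$ncol)
  eqs <- lapply(grid$habitat$mortality_factor, function(phi) {
    class_equilibrium(config, phi)
  })
  cls <- as.vector(grid$class)[cells]
  cover <- grid$habitat$cover[cls]
  fem <- vapply(eqs, `[[`, numeric(1), "females")
  mal <- vapply(eqs, `[[`, numeric(1), "males")
  cc <- cell_coords(grid, cells)
  tibble::tibble(
    cell = cc$cell, row = cc$row, col = cc$col,
    class = .class_levels[cls],
    males = mal[cls] * cover,
    females = fem[cls] * cover
  )
}
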