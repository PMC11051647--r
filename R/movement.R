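#' Mean displacement of a lazy orthogonal lattice walk (exact)
#'
#' Computes, by exact convolution of the step distribution, the expected
#' Euclidean displacement (in cells = km) after `steps` days of a random
#' walk on the unit lattice in which a walker moves to one of the four
#' orthogonal neighbours with total probability `p` (p/4 each) and otherwise
#' stays put.
#'
#' @param p Daily evacuation probability in \[0, 1\].
#' @param steps Number of days (>= 1).
#' @return Expected absolute displacement in km.
#' @export
mean_walk_displacement <- function(p, steps) {
  stopifnot(p >= 0, p <= 1, steps >= 1)
  if (p == 0) return(0)
  n <- as.integer(steps)
  w <- 2L * n + 1L
  dist <- matrix(0, w, w)
  mid <- n + 1L
  dist[mid, mid] <- 1
  for (t in seq_len(n)) {
    up <- rbind(dist[-1, , drop = FALSE], 0)
    dn <- rbind(0, dist[-w, , drop = FALSE])
    lt <- cbind(dist[, -1, drop = FALSE], 0)
    rt <- cbind(0, dist[, -w, drop = FALSE])
    dist <- (1 - p) * dist + (p / 4) * (up + dn + lt + rt)
  }
  dx <- matrix(rep(-n:n, w), w, w)
  dy <- t(dx)
  sum(dist * sqrt(dx^2 + dy^2))
}

#' Calibrate the daily cell-evacuation probability
#'
#' Finds the daily probability `p` of leaving a cell such that an
#' unconstrained orthogonal walk attains a mean absolute displacement of
#' `nominal * sqrt(horizon)` km after `horizon` days.  The diffusive
#' (square-root-of-time) target is used because a fixed daily step rate on a
#' 1-km lattice badly misstates long-run spread if matched over only a day
#' or two; assessing the rate over a 30-day horizon keeps the simulated
#' spread consistent with field dispersal estimates.
#'
#' @param nominal Nominal daily displacement in km/day (>= 0).
#' @param horizon Calibration horizon in days (standard 30).
#' @return Daily evacuation probability in \[0, 1\].
#' @examples
#' calibrate_evacuation(0.4, 30)
#' @export
calibrate_evacuation <- function(nominal, horizon = 30) {
  stopifnot(nominal >= 0, horizon >= 1)
  if (nominal == 0) return(0)
  target <- nominal * sqrt(horizon)
  dmax <- mean_walk_displacement(1, horizon)
  if (target > dmax) {
    stop("nominal displacement ", nominal, " km/day is unattainable: ",
         "no evacuation probability <= 1 achieves it", call. = FALSE)
  }
  uniroot(function(p) mean_walk_displacement(p, horizon) - target,
          lower = 0, upper = 1, tol = 1e-10)$root
}

#' Age- and sex-dependent evacuation probabilities
#'
#' Females move a nominal 0.2 km/day at age 1, rising linearly to 0.4 km/day
#' at age 10 as the wing muscles develop, constant thereafter; males move
#' half as much at every age.  Each distinct nominal displacement is
#' calibrated once via [calibrate_evacuation()].
#'
#' @param config A `tsetse_config`.
#' @return List with numeric vectors `female` and `male` of length
#'   `max_adult_age`: the daily evacuation probability by age class.
#' @export
evacuation_table <- function(config) {
  mob <- config$mobility
  A <- config$demography$max_adult_age
  a <- seq_len(A)
  ramp <- pmin(a, mob$mature_age)
  disp_f <- mob$displacement_age1 +
    (ramp - 1) / max(mob$mature_age - 1, 1) *
      (mob$displacement_max - mob$displacement_age1)
  disp_m <- disp_f * mob$male_multiplier
  if (!isTRUE(mob$enabled)) {
    return(list(female = numeric(A), male = numeric(A)))
  }
  all_disp <- c(disp_f, disp_m)
  uni <- sort(unique(all_disp))
  p_uni <- vapply(uni, calibrate_evacuation, numeric(1),
                  horizon = mob$calibration_horizon)
  list(female = p_uni[match(disp_f, uni)],
       male = p_uni[match(disp_m, uni)])
}

#' Directional damping of movement between adjacent cells
#'
#' The evacuation rate toward an orthogonal neighbour is damped when the
#' destination has less habitat: for a move between riverine cells with
#' lower cover at the destination the factor is `cover(to) / cover(from)`
#' (e.g. 0.7 from a large to a medium river); for a move from a riverine
#' cell into an interfluve it is the interfluve entry factor (standard 0.01,
#' i.e. 99 percent of would-be emigrants turn back); moves toward equal or
#' better habitat - including interfluve to river and small to larger river
#' - are never damped.  Damped flies return to the centre of their origin
#' cell the same day.
#'
#' @param grid A `tsetse_grid`.
#' @param from,to Cell ids (column-major) of orthogonally adjacent cells;
#'   vectors are paired elementwise.
#' @param config A `tsetse_config`.
#' @return Numeric multiplier(s) in \[0, 1\].
#' @export
directional_factor <- function(grid, from, to, config = standard_config()) {
  cf <- cell_coords(grid, from)
  ct <- cell_coords(grid, to)
  if (any(abs(cf$row - ct$row) + abs(cf$col - ct$col) != 1)) {
    stop("cells must be orthogonally adjacent", call. = FALSE)
  }
  cls_f <- as.vector(grid$class)[from]
  cls_t <- as.vector(grid$class)[to]
  cov <- grid$habitat$cover
  fac <- rep(1, length(from))
  into_interfluve <- cls_t == 4L & cls_f != 4L
  fac[into_interfluve] <- config$mobility$interfluve_entry_factor
  downgrade <- !into_interfluve & cls_f != 4L &
    cov[cls_t] < cov[cls_f]
  fac[downgrade] <- (cov[cls_t] / cov[cls_f])[downgrade]
  fac
}

#' Movement operator of a landscape
#'
#' Sparse linear operator `A` such that one day of movement of a cohort
#' with evacuation probability `p` maps cell counts `x` to `x + p * A x`.
#' Off-diagonal entries are `directional_factor / 4` for each orthogonal
#' neighbour pair; the diagonal removes the corresponding outflow, so
#' column sums are zero and movement conserves flies exactly.  Grid edges
#' reflect: flies that would leave the map stay in their cell.
#'
#' @param grid A `tsetse_grid`.
#' @param config A `tsetse_config`.
#' @return A `dgCMatrix` of dimension ncell x ncell.
#' @export
movement_matrix <- function(grid, config = standard_config()) {
  nr <- grid$nrow
  nc <- grid$ncol
  n <- nr * nc
  cc <- cell_coords(grid, seq_len(n))
  from <- integer(0)
  to <- integer(0)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r2 <- cc$row + d[1]
    c2 <- cc$col + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    from <- c(from, cc$cell[ok])
    to <- c(to, cell_index(grid, r2[ok], c2[ok]))
  }
  fac <- directional_factor(grid, from, to, config) / 4
  A <- Matrix::sparseMatrix(i = to, j = from, x = fac, dims = c(n, n))
  out <- Matrix::colSums(A)
  A - Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n), x = out,
                           dims = c(n, n))
}
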