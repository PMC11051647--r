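#' Percent of the pre-control population remaining
#'
#' For each cell, 100 times the mean over the window of the daily ratio of
#' pooled (males plus females) adults to the pre-control baseline.  The
#' standard reporting window is the 183 days following the last refreshment
#' of the targets.  Cells with a zero baseline have no defined percentage
#' and are reported as `NA`.
#'
#' @param run A `tsetse_run`.
#' @param baseline Per-cell pre-control pooled adult counts (e.g.
#'   [baseline_population()] of the burn-in state), length ncell.
#' @param window Days (as in `run$days`) to average over; default the last
#'   183 recorded days.
#' @param cells Cells to report; default all recorded cells.
#' @return Tibble: cell, baseline, pct_remaining.
#' @export
percent_remaining <- function(run, baseline, window = NULL, cells = NULL) {
  if (is.null(run$cell_adults)) {
    stop("run was recorded without per-cell series", call. = FALSE)
  }
  if (is.null(window)) window <- tail(run$days, 183)
  idx <- match(window, run$days)
  if (anyNA(idx)) stop("window contains unrecorded days", call. = FALSE)
  cells <- cells %||% run$cells
  rows <- match(cells, run$cells)
  if (anyNA(rows)) stop("cells not recorded in this run", call. = FALSE)
  b <- baseline[cells]
  sub <- run$cell_adults[rows, idx, drop = FALSE]
  pct <- 100 * rowMeans(sub / b)
  pct[b <= 0] <- NA_real_
  tibble::tibble(cell = cells, baseline = b, pct_remaining = pct)
}

#' Fraction of the population meeting an age condition
#'
#' Percentage of the adult population of a cell set whose age satisfies
#' `comparator threshold` (for example `>= 10` days, the proxy for
#' availability to stationary baits, or `> 40` days, the oldest age the
#' ovarian method can resolve).
#'
#' @param state A `tsetse_state`.
#' @param cells Cell ids to pool; default all.
#' @param threshold Age threshold in days.
#' @param comparator One of `">="`, `">"`, `"<"`, `"<="`.
#' @param sex `"pooled"`, `"female"` or `"male"`.
#' @return Percentage in \[0, 100\], or `NA` if the population is empty.
#' @export
age_fraction <- function(state, cells = NULL, threshold = 10,
                         comparator = c(">=", ">", "<", "<="),
                         sex = c("pooled", "female", "male")) {
  comparator <- match.arg(comparator)
  sex <- match.arg(sex)
  A <- ncol(state$F)
  stopifnot(threshold >= 1, threshold <= A)
  cells <- cells %||% seq_len(nrow(state$F))
  pop <- switch(sex,
    pooled = state$F[cells, , drop = FALSE] + state$M[cells, , drop = FALSE],
    female = state$F[cells, , drop = FALSE],
    male = state$M[cells, , drop = FALSE])
  byage <- colSums(pop)
  tot <- sum(byage)
  if (tot <= 0) return(NA_real_)
  ages <- seq_len(A)
  sel <- switch(comparator, ">=" = ages >= threshold, ">" = ages > threshold,
                "<" = ages < threshold, "<=" = ages <= threshold)
  100 * sum(byage[sel]) / tot
}

#' Daily pupal production per 1000 females
#'
#' 1000 times the daily ratio of pupae deposited to the female population,
#' averaged over a window of recorded days.  Days with no females
#' contribute nothing; if the whole window has no females the result is
#' `NA`.
#'
#' @param run A `tsetse_run`.
#' @param window Days to average over; default all recorded days.
#' @return Pupae per 1000 females per day.
#' @export
pupal_production_rate <- function(run, window = NULL) {
  rec <- run$records
  if (!is.null(window)) rec <- rec[rec$day %in% window, ]
  ok <- rec$females > 0
  if (!any(ok)) return(NA_real_)
  mean(1000 * rec$pupae_deposited[ok] / rec$females[ok])
}

#' Along-river transect of a per-cell metric
#'
#' Orders a per-cell metric along one river from its source to its mouth,
#' for Fig-4-style profiles of control along a monitored river.
#'
#' @param grid A `tsetse_grid`.
#' @param river River name.
#' @param values A tibble with a `cell` column and one or more value
#'   columns (e.g. the output of [percent_remaining()]), or a named
#'   numeric vector indexed by cell id.
#' @return Tibble of the river's cells ordered by position from the
#'   source, joined with the value column(s).
#' @export
transect <- function(grid, river, values) {
  rc <- river_cells(grid, river)
  if (is.numeric(values)) {
    values <- tibble::tibble(cell = as.integer(names(values)),
                             value = unname(values))
  }
  dplyr::left_join(rc, values, by = "cell")
}

#' Global daily percent of old females in a run
#'
#' Convenience series derived from the recorded global female age
#' distribution: the percentage of females older than `threshold` days on
#' each recorded day.
#'
#' @param run A `tsetse_run`.
#' @param threshold Age in days (default the configured old age, 40).
#' @param sex `"female"` or `"male"`.
#' @return Tibble: day, pct_old.
#' @export
old_age_series <- function(run, threshold = run$config$metrics$old_age,
                           sex = c("female", "male")) {
  sex <- match.arg(sex)
  m <- if (sex == "female") run$female_by_age else run$male_by_age
  tot <- colSums(m)
  old <- colSums(m[(threshold + 1):nrow(m), , drop = FALSE])
  tibble::tibble(day = run$days,
                 pct_old = ifelse(tot > 0, 100 * old / tot, NA_real_))
}
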