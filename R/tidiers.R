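#' Tidy the daily records of a run
#'
#' @param x A `tsetse_run`.
#' @param cells If `TRUE`, return the per-cell daily series in long format
#'   (columns day, cell, adults, females, females_old, adults_mobile)
#'   instead of the global daily records.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tsetse_run <- function(x, cells = FALSE, ...) {
  if (!cells) return(x$records)
  if (is.null(x$cell_adults)) {
    stop("run was recorded without per-cell series", call. = FALSE)
  }
  nd <- length(x$days)
  tibble::tibble(
    day = rep(x$days, each = length(x$cells)),
    cell = rep(x$cells, nd),
    adults = as.vector(x$cell_adults),
    females = as.vector(x$cell_females),
    females_old = as.vector(x$cell_females_old),
    adults_mobile = as.vector(x$cell_adults_mobile)
  )
}

#' One-row summary of a run
#'
#' @param x A `tsetse_run`.
#' @param ... Unused.
#' @return A tibble with the run span, final population totals and the
#'   overall female kill imposed by targets.
#' @export
glance.tsetse_run <- function(x, ...) {
  rec <- x$records
  tibble::tibble(
    days = nrow(rec),
    first_day = min(rec$day), last_day = max(rec$day),
    final_females = tail(rec$females, 1),
    final_males = tail(rec$males, 1),
    final_adults = tail(rec$adults, 1),
    mean_kill_frac_female = mean(rec$kill_frac_female[rec$control_active]),
    pupae_per_1000f = pupal_production_rate(x)
  )
}

#' @rdname tidy.tsetse_run
#' @export
tidy.tsetse_scenario <- function(x, ...) {
  dplyr::bind_rows(lapply(x$phases, function(r) r$records), .id = "phase")
}

#' @rdname glance.tsetse_run
#' @export
glance.tsetse_scenario <- function(x, ...) {
  dplyr::bind_rows(lapply(x$phases, glance.tsetse_run), .id = "phase")
}

#' Plot a habitat map
#'
#' @param object A `tsetse_grid`.
#' @param ... Unused.
#' @return A ggplot: one tile per cell coloured by habitat class, with the
#'   operational region outlined.
#' @export
autoplot.tsetse_grid <- function(object, ...) {
  cells <- tidy(object)
  op <- object$operational
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      large_river = "#08519c", medium_river = "#3182bd",
      small_river = "#9ecae1", interfluve = "#f7f4ef")) +
    ggplot2::annotate("rect", xmin = min(op$cols) - 0.5,
                      xmax = max(op$cols) + 0.5,
                      ymin = min(op$rows) - 0.5, ymax = max(op$rows) + 0.5,
                      fill = NA, colour = "grey40", linetype = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (km)", y = "row (km, row 1 = North)",
                  fill = "habitat")
}

#' Plot the daily population trajectory of a run
#'
#' @param object A `tsetse_run`.
#' @param ... Unused.
#' @return A ggplot of daily female and male totals on a log scale.
#' @export
autoplot.tsetse_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$records[, c("day", "females", "males")],
                              -"day", names_to = "sex",
                              values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$count,
                                     colour = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day", y = "adults (log scale)")
}

#' Plot a transect of percent remaining along a river
#'
#' @param tr Output of [transect()] with a `pct_remaining` column.
#' @return A ggplot of the metric against distance from the source.
#' @export
plot_transect <- function(tr) {
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$position,
                                   y = .data$pct_remaining)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class)) +
    ggplot2::labs(x = "distance from source (km)",
                  y = "% of pre-control population remaining")
}
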