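#' Read / write a simulation configuration as YAML
#'
#' The file holds the `demography`, `mobility`, `burn_in` and `metrics`
#' lists of [standard_config()]; absent fields keep their standard values.
#' Derived (solved) quantities are never written: they are recomputed by
#' [prepare_config()].
#'
#' @param path File path.
#' @return `read_config` returns a `tsetse_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- standard_config(demography = y$demography %||% list(),
                         mobility = y$mobility %||% list())
  for (nm in intersect(names(y$burn_in), names(cfg$burn_in))) {
    cfg$burn_in[[nm]] <- y$burn_in[[nm]]
  }
  for (nm in intersect(names(y$metrics), names(cfg$metrics))) {
    cfg$metrics[[nm]] <- y$metrics[[nm]]
  }
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config A `tsetse_config`.
#' @export
write_config <- function(config, path) {
  dem <- config$demography
  dem <- dem[!vapply(dem, is.null, logical(1))]
  yaml::write_yaml(list(demography = dem, mobility = config$mobility,
                        burn_in = config$burn_in,
                        metrics = config$metrics), path)
  invisible(path)
}

#' Read / write a river-network specification as YAML
#'
#' The spec is a list of rivers, each with a `name` and a list of
#' axis-aligned `waypoints` (`[row, col]`, 1-based, row 1 at North), in the
#' form accepted by [build_schematic_map()].
#'
#' @param path File path.
#' @return `read_network_spec` returns a named list of waypoint matrices.
#' @export
read_network_spec <- function(path) {
  y <- yaml::read_yaml(path)
  rivers <- y$rivers %||% y
  out <- lapply(rivers, function(r) {
    wp <- r$waypoints %||% r
    do.call(rbind, lapply(wp, function(w) as.numeric(w[1:2])))
  })
  names(out) <- vapply(rivers, function(r) r$name %||% "", character(1))
  if (any(names(out) == "")) {
    names(out)[names(out) == ""] <-
      paste0("river", seq_len(sum(names(out) == "")))
  }
  out
}

#' @rdname read_network_spec
#' @param network Named list of waypoint matrices.
#' @export
write_network_spec <- function(network, path) {
  rivers <- lapply(names(network), function(nm) {
    wp <- network[[nm]]
    list(name = nm,
         waypoints = lapply(seq_len(nrow(wp)),
                            function(i) as.integer(wp[i, ])))
  })
  yaml::write_yaml(list(rivers = rivers), path)
  invisible(path)
}

#' Read / write a deployment plan as YAML
#'
#' @param path File path.
#' @param grid Grid used to translate `(row, col)` treated-cell entries.
#' @return `read_plan` returns a [deployment_plan()].
#' @export
read_plan <- function(path, grid) {
  y <- yaml::read_yaml(path)
  cells <- if (!is.null(y$cells)) {
    as.integer(unlist(y$cells))
  } else {
    rc <- do.call(rbind, lapply(y$treated, function(w) as.integer(w[1:2])))
    cell_index(grid, rc[, 1], rc[, 2])
  }
  deployment_plan(cells,
                  start_day = y$start_day, end_day = y$end_day,
                  schedule = y$schedule %||% 0.05,
                  targets_per_cell = y$targets_per_cell %||% 20,
                  degradation_rate = y$degradation_rate %||% 0.015,
                  refresh_period = y$refresh_period %||% 183,
                  name = y$name)
}

#' @rdname read_plan
#' @param plan A [deployment_plan()].
#' @export
write_plan <- function(plan, path) {
  yaml::write_yaml(list(
    name = plan$name, cells = as.integer(plan$cells),
    start_day = plan$start_day, end_day = plan$end_day,
    schedule = plan$schedule$name_rate,
    targets_per_cell = plan$targets_per_cell,
    degradation_rate = plan$degradation_rate,
    refresh_period = plan$refresh_period), path)
  invisible(path)
}
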