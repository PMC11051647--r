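#' Schematic NW-Uganda-style study landscape
#'
#' A hand-authored 70 x 70 schematic river network reproducing the
#' qualitative features of the study area the model was built for: a
#' North-South watershed near the western edge with sparse vegetation,
#' rivers draining East, interfluves typically two cells wide between
#' neighbouring rivers, and named monitoring plots.  It is an
#' approximation authored for this package - the real river layout is not
#' available as data - so absolute per-cell results depend on it while the
#' qualitative patterns (upstream/downstream contrast, invasion from
#' untreated rivers, knock-on control beyond treated sections) do not.
#'
#' Plots: five riverine plots treated in the first phase (ayi, inve, goro,
#' aiivu, ewal - aiivu lies on the large-river section of the long "chosen"
#' river), plus the untreated oluffe plot 3 km from treated rivers to its
#' North and South, and the koboko plot far North on a separate river.
#' Each plot spans 13 monitored km of river: 3 upstream cells, 7 central
#' (treated) cells and 3 downstream cells.
#'
#' @param habitat Habitat class table, see [habitat_classes()].
#' @return A `tsetse_grid` with attribute `plots` (see [uganda_plots()]).
#' @examples
#' g <- uganda_schematic()
#' table(habitat_of(g))
#' @export
uganda_schematic <- function(habitat = habitat_classes()) {
  network <- list(
    kochi = rbind(c(8, 14), c(8, 66)),
    ayi = rbind(c(20, 10), c(20, 66)),
    oru = rbind(c(23, 14), c(23, 40), c(26, 40)),
    inve = rbind(c(26, 10), c(26, 66)),
    trib_north = rbind(c(32, 12), c(32, 24), c(38, 24)),
    chosen = rbind(c(38, 9), c(38, 66)),
    trib_south = rbind(c(44, 12), c(44, 30), c(38, 30)),
    goro = rbind(c(50, 12), c(50, 66)),
    ewal = rbind(c(56, 14), c(56, 66)),
    drc_north = rbind(c(30, 6), c(30, 2)),
    drc_south = rbind(c(48, 6), c(48, 2))
  )
  grid <- build_schematic_map(network, nrow = 70, ncol = 70,
                              habitat = habitat)
  plot_def <- tibble::tibble(
    plot = c("ayi", "oluffe", "inve", "aiivu", "goro", "ewal", "koboko"),
    river = c("ayi", "oru", "inve", "chosen", "goro", "ewal", "kochi"),
    row = c(20, 23, 26, 38, 50, 56, 8),
    col_from = c(19, 22, 19, 41, 22, 27, 20),
    treated = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  plots <- dplyr::bind_rows(lapply(seq_len(nrow(plot_def)), function(i) {
    d <- plot_def[i, ]
    cols <- d$col_from + 0:12
    tibble::tibble(
      plot = d$plot, river = d$river, row = d$row, col = cols,
      cell = cell_index(grid, rep(d$row, 13), cols),
      offset = 1:13,
      role = rep(c("upstream", "treated", "downstream"), c(3, 7, 3)),
      treated = d$treated & rep(c(FALSE, TRUE, FALSE), c(3, 7, 3))
    )
  }))
  attr(grid, "plots") <- plots
  grid
}

#' Monitoring plots of the schematic landscape
#'
#' @param grid A grid from [uganda_schematic()].
#' @return Tibble with one row per monitored cell: plot, river, row, col,
#'   cell, offset (1-13 along the monitored stretch, source side first),
#'   role (upstream / treated / downstream) and whether the cell is
#'   treated in the first phase.
#' @export
uganda_plots <- function(grid) {
  p <- attr(grid, "plots")
  if (is.null(p)) stop("grid has no plot table; use uganda_schematic()",
                       call. = FALSE)
  p
}

#' Phased deployment plans for the schematic landscape
#'
#' Five successive deployment phases of the kind used in the NW-Uganda
#' campaign: a first year of targets in the five treated plots only, then
#' four two-year phases in which the deployments expand a little (phase
#' 2, including the previously untreated oluffe plot), expand much
#' further North and East to the most extensive coverage (phase 3,
#' including koboko's river), contract slightly in the North (phase 4),
#' and finally stop in the South-West invasion area (phase 5).  Years are
#' 366 days (two 183-day target cycles) so the six-month reporting window
#' fits exactly.
#'
#' @param grid A grid from [uganda_schematic()].
#' @param schedule Kill schedule (or its name rate) for every phase.
#' @param degradation_rate Daily target degradation for every phase.
#' @param targets_per_cell Targets per treated cell.
#' @return Named list of five [deployment_plan()]s.
#' @export
phase_plans <- function(grid, schedule = 0.05, degradation_rate = 0.015,
                        targets_per_cell = 20) {
  plots <- uganda_plots(grid)
  riv <- function(nm, cols) {
    rc <- river_cells(grid, nm)
    rc$cell[rc$col %in% cols]
  }
  p1 <- plots$cell[plots$treated]
  p2 <- unique(c(
    riv("ayi", 22:40), riv("oru", 22:40), riv("inve", 22:40),
    riv("chosen", 38:56), riv("goro", 22:40), riv("ewal", 27:42)
  ))
  p3 <- unique(c(
    riv("kochi", 20:44),
    riv("ayi", 14:60), riv("oru", 16:40), riv("inve", 14:60),
    riv("chosen", 12:60), riv("trib_north", 14:24), riv("trib_south", 14:30),
    riv("goro", 14:60), riv("ewal", 16:60)
  ))
  p4 <- unique(c(
    riv("kochi", 20:38),
    riv("ayi", 14:60), riv("oru", 16:40), riv("inve", 14:60),
    riv("chosen", 12:60), riv("trib_north", 14:24), riv("trib_south", 12:30),
    riv("goro", 14:60), riv("ewal", 16:62)
  ))
  co <- cell_coords(grid, p4)
  p5 <- p4[!(co$col <= 30 & co$row >= 38)]
  yr <- 366
  mk <- function(cells, start, end, nm) {
    deployment_plan(cells, start_day = start, end_day = end,
                    schedule = schedule,
                    targets_per_cell = targets_per_cell,
                    degradation_rate = degradation_rate, name = nm)
  }
  list(
    phase1 = mk(p1, 1, yr, "phase1"),
    phase2 = mk(p2, yr + 1, yr + 2 * 366, "phase2"),
    phase3 = mk(p3, yr + 2 * 366 + 1, yr + 4 * 366, "phase3"),
    phase4 = mk(p4, yr + 4 * 366 + 1, yr + 6 * 366, "phase4"),
    phase5 = mk(p5, yr + 6 * 366 + 1, yr + 8 * 366, "phase5")
  )
}
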