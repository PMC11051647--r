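#' Habitat class table
#'
#' The four habitat classes of the landscape model, with the fraction of each
#' cell covered by good tsetse habitat and the multiplier applied to natural
#' death rates relative to the best (large-river) habitat.  Standard values:
#' covers 0.10, 0.07, 0.04, 0.01 and mortality factors 1.00, 1.05, 1.10, 1.20
#' for large river, medium river, small river and interfluve respectively.
#'
#' @param cover Numeric length 4, fraction of cell area that is good habitat,
#'   in class order large river, medium river, small river, interfluve.  Each
#'   must lie in (0, 1].
#' @param mortality_factor Numeric length 4, multiplier (>= 1) on natural
#'   death rates at carrying capacity, same order.
#' @return A tibble with columns `class`, `code`, `cover`, `mortality_factor`.
#' @examples
#' habitat_classes()
#' @export
habitat_classes <- function(cover = c(0.10, 0.07, 0.04, 0.01),
                            mortality_factor = c(1.00, 1.05, 1.10, 1.20)) {
  stopifnot(length(cover) == 4, length(mortality_factor) == 4)
  if (any(cover <= 0) || any(cover > 1)) {
    stop("habitat cover must lie in (0, 1]", call. = FALSE)
  }
  if (any(mortality_factor < 1)) {
    stop("mortality factors must be >= 1", call. = FALSE)
  }
  tibble::tibble(
    class = c("large_river", "medium_river", "small_river", "interfluve"),
    code = c("L", "M", "S", "I"),
    cover = as.numeric(cover),
    mortality_factor = as.numeric(mortality_factor)
  )
}

.class_levels <- c("large_river", "medium_river", "small_river", "interfluve")
.class_codes <- c("L", "M", "S", "I")

#' Expand an axis-aligned waypoint polyline to a cell path
#'
#' @param waypoints Two-column matrix of (row, col) waypoints.
#' @return Integer matrix of consecutive (row, col) cells.
#' @keywords internal
#' @noRd
expand_path <- function(waypoints, name = "river") {
  wp <- matrix(as.integer(round(waypoints)), ncol = 2)
  if (nrow(wp) < 1) stop("empty waypoint list for ", name, call. = FALSE)
  if (nrow(wp) == 1) return(wp)
  out <- wp[1, , drop = FALSE]
  for (i in 2:nrow(wp)) {
    a <- wp[i - 1, ]
    b <- wp[i, ]
    if (a[1] != b[1] && a[2] != b[2]) {
      stop("river '", name, "' has a diagonal leg: all legs must be ",
           "axis-aligned (parallel or at right angles)", call. = FALSE)
    }
    if (a[1] == b[1]) {
      cols <- seq(a[2], b[2])
      leg <- cbind(rep(a[1], length(cols)), cols)
    } else {
      rows <- seq(a[1], b[1])
      leg <- cbind(rows, rep(a[2], length(rows)))
    }
    out <- rbind(out, leg[-1, , drop = FALSE])
  }
  out
}

#' Build a schematic river-network landscape
#'
#' Constructs a gridded habitat map from a list of axis-aligned river
#' polylines.  Each river is traced from its source; a cell's class is set by
#' its distance from the source measured along the longest upstream path
#' (so a confluence takes the class implied by its largest upstream length):
#' the first `small_length` cells are small river, the next `medium_length`
#' are medium river, and all further cells are large river.  Every cell not
#' traversed by a river is interfluve.  Tributaries are declared by ending a
#' river's path on a cell of another river.
#'
#' @param network A named list of rivers.  Each element is either a
#'   two-column (row, col) waypoint matrix or a list with element
#'   `waypoints`.  Waypoints are 1-based grid coordinates, row 1 at the
#'   North edge; consecutive waypoints must share a row or a column.
#' @param nrow,ncol Grid dimensions in cells (standard 70 x 70).
#' @param habitat Habitat class table, see [habitat_classes()].
#' @param operational_margin Width in cells of the border band around the
#'   operational region (standard 10, leaving a central 50 x 50 block).
#' @param small_length Cells a river spans before turning medium (standard 7).
#' @param medium_length Further cells before turning large (standard 21).
#' @return An object of class `tsetse_grid`: a list with the class matrix
#'   (`class`, integer codes 1 = large river ... 4 = interfluve), the
#'   `habitat` table, a `rivers` tibble (river, position from source, row,
#'   col, cell, dist, class) and the `operational` region bounds.
#' @examples
#' g <- build_schematic_map(list(r = rbind(c(5, 2), c(5, 15))), 10, 16)
#' table(habitat_of(g))
#' @export
build_schematic_map <- function(network, nrow = 70, ncol = 70,
                                habitat = habitat_classes(),
                                operational_margin = 10,
                                small_length = 7, medium_length = 21) {
  stopifnot(nrow >= 1, ncol >= 1)
  if (is.null(names(network)) && length(network) > 0) {
    names(network) <- paste0("river", seq_along(network))
  }
  paths <- lapply(seq_along(network), function(i) {
    r <- network[[i]]
    wp <- if (is.list(r) && !is.null(r$waypoints)) r$waypoints else r
    p <- expand_path(as.matrix(wp), names(network)[i])
    if (any(p[, 1] < 1 | p[, 1] > nrow | p[, 2] < 1 | p[, 2] > ncol)) {
      stop("river '", names(network)[i], "' leaves the grid", call. = FALSE)
    }
    p
  })
  names(paths) <- names(network)

  cell_of <- function(r, c) r + (c - 1L) * as.integer(nrow)
  # longest distance-from-source per cell over the merged river DAG
  edges_from <- integer(0)
  edges_to <- integer(0)
  all_cells <- integer(0)
  for (p in paths) {
    ids <- cell_of(p[, 1], p[, 2])
    if (anyDuplicated(ids)) {
      stop("a river revisits a cell; paths must not self-intersect",
           call. = FALSE)
    }
    all_cells <- c(all_cells, ids)
    if (length(ids) > 1) {
      edges_from <- c(edges_from, ids[-length(ids)])
      edges_to <- c(edges_to, ids[-1])
    }
  }
  nodes <- unique(all_cells)
  dist <- setNames(rep(1L, length(nodes)), nodes)
  if (length(edges_from)) {
    indeg <- table(factor(as.character(edges_to), levels = as.character(nodes)))
    queue <- nodes[indeg == 0]
    seen <- 0L
    indeg <- as.integer(indeg)
    names(indeg) <- as.character(nodes)
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      seen <- seen + 1L
      out <- edges_to[edges_from == u]
      for (v in out) {
        vv <- as.character(v)
        dist[vv] <- max(dist[vv], dist[as.character(u)] + 1L)
        indeg[vv] <- indeg[vv] - 1L
        if (indeg[vv] == 0L) queue <- c(queue, v)
      }
    }
    if (seen < length(nodes)) {
      stop("river network contains a cycle", call. = FALSE)
    }
  }

  classify <- function(d) {
    ifelse(d <= small_length, 3L,
           ifelse(d <= small_length + medium_length, 2L, 1L))
  }
  class_mat <- matrix(4L, nrow, ncol)
  if (length(nodes)) {
    class_mat[nodes] <- classify(as.integer(dist[as.character(nodes)]))
  }

  rivers <- if (length(paths)) {
    dplyr::bind_rows(lapply(names(paths), function(nm) {
      p <- paths[[nm]]
      ids <- cell_of(p[, 1], p[, 2])
      tibble::tibble(
        river = nm, position = seq_len(base::nrow(p)),
        row = p[, 1], col = p[, 2], cell = ids,
        dist = as.integer(dist[as.character(ids)]),
        class = .class_levels[class_mat[ids]]
      )
    }))
  } else {
    tibble::tibble(river = character(), position = integer(),
                   row = integer(), col = integer(), cell = integer(),
                   dist = integer(), class = character())
  }

  m <- operational_margin
  op <- list(rows = seq.int(m + 1L, max(m + 1L, nrow - m)),
             cols = seq.int(m + 1L, max(m + 1L, ncol - m)))
  structure(
    list(class = class_mat, nrow = as.integer(nrow), ncol = as.integer(ncol),
         habitat = habitat, rivers = rivers, operational = op,
         small_length = small_length, medium_length = medium_length),
    class = "tsetse_grid"
  )
}

#' Homogeneous single-class landscape
#'
#' A grid in which every cell belongs to one habitat class, as used for the
#' parameterisation experiments in an effectively infinite best-habitat
#' landscape (every cell is then equivalent to a map-centre cell: with a
#' uniform population, reflecting edges and equal neighbours, movement has
#' no net effect anywhere).
#'
#' @param nrow,ncol Grid dimensions.
#' @param class Habitat class name (default `"large_river"`).
#' @param habitat Habitat class table.
#' @return A `tsetse_grid` with an empty river table.
#' @export
homogeneous_grid <- function(nrow = 9, ncol = 9, class = "large_river",
                             habitat = habitat_classes()) {
  ic <- match(class, .class_levels)
  if (is.na(ic)) stop("unknown habitat class '", class, "'", call. = FALSE)
  g <- build_schematic_map(list(), nrow = nrow, ncol = ncol,
                           habitat = habitat, operational_margin = 0)
  g$class[] <- ic
  g
}

#' @export
print.tsetse_grid <- function(x, ...) {
  tab <- table(factor(.class_levels[x$class], levels = .class_levels))
  cat("<tsetse_grid> ", x$nrow, "x", x$ncol, " cells, ",
      length(unique(x$rivers$river)), " rivers\n", sep = "")
  print(tab)
  invisible(x)
}

#' Habitat class of each cell
#'
#' @param grid A `tsetse_grid`.
#' @param cells Optional cell ids (column-major); default all cells.
#' @return Character vector of class names.
#' @export
habitat_of <- function(grid, cells = NULL) {
  v <- .class_levels[grid$class]
  if (is.null(cells)) v else v[cells]
}

#' Per-cell habitat cover and mortality factor
#' @keywords internal
#' @noRd
grid_cover <- function(grid) grid$habitat$cover[as.vector(grid$class)]

#' @noRd
grid_mortality_factor <- function(grid) {
  grid$habitat$mortality_factor[as.vector(grid$class)]
}

#' Cell ids from (row, col)
#'
#' @param grid A `tsetse_grid`.
#' @param row,col Integer vectors of 1-based coordinates, row 1 at North.
#' @return Column-major cell indices into the class matrix.
#' @export
cell_index <- function(grid, row, col) {
  stopifnot(all(row >= 1), all(row <= grid$nrow),
            all(col >= 1), all(col <= grid$ncol))
  as.integer(row + (col - 1L) * grid$nrow)
}

#' @rdname cell_index
#' @param cell Cell ids to convert back to coordinates.
#' @export
cell_coords <- function(grid, cell) {
  tibble::tibble(cell = as.integer(cell),
                 row = as.integer((cell - 1L) %% grid$nrow + 1L),
                 col = as.integer((cell - 1L) %/% grid$nrow + 1L))
}

#' Cells of one river, ordered source to mouth
#'
#' @param grid A `tsetse_grid`.
#' @param river River name as used in the network spec.
#' @return Tibble of river cells ordered by position from the source.
#' @export
river_cells <- function(grid, river) {
  if (!river %in% grid$rivers$river) {
    stop("unknown river '", river, "'", call. = FALSE)
  }
  dplyr::arrange(dplyr::filter(grid$rivers, .data$river == !!river),
                 .data$position)
}

#' Tidy a landscape grid into a cell tibble
#'
#' @param x A `tsetse_grid`.
#' @param ... Unused.
#' @return Tibble with one row per cell: cell, row, col, class, cover,
#'   mortality_factor, operational flag.
#' @export
tidy.tsetse_grid <- function(x, ...) {
  n <- x$nrow * x$ncol
  cc <- cell_coords(x, seq_len(n))
  cls <- as.vector(x$class)
  tibble::tibble(
    cell = cc$cell, row = cc$row, col = cc$col,
    class = .class_levels[cls],
    cover = x$habitat$cover[cls],
    mortality_factor = x$habitat$mortality_factor[cls],
    operational = cc$row %in% x$operational$rows &
      cc$col %in% x$operational$cols
  )
}

#' Write / read a habitat grid as plain-text CSV of class codes
#'
#' The file holds one row per grid row (North first), cells encoded by the
#' single-character habitat codes L, M, S, I, comma-separated.  Only the
#' class map is stored: river identities and positions are not representable
#' in this format, so a read grid carries an empty river table.
#'
#' @param grid A `tsetse_grid`.
#' @param path File path.
#' @return `write_grid` returns `path` invisibly; `read_grid` returns a
#'   `tsetse_grid`.
#' @export
write_grid <- function(grid, path) {
  codes <- matrix(.class_codes[grid$class], grid$nrow, grid$ncol)
  lines <- apply(codes, 1, paste, collapse = ",")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_grid
#' @param habitat Habitat class table used to interpret the codes.
#' @param operational_margin Border band width, as in
#'   [build_schematic_map()].
#' @export
read_grid <- function(path, habitat = habitat_classes(),
                      operational_margin = 10) {
  lines <- readLines(path)
  rows <- strsplit(lines, ",", fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    stop("ragged rows in grid file '", path, "'", call. = FALSE)
  }
  flat <- unlist(rows)
  bad <- setdiff(unique(flat), .class_codes)
  if (length(bad)) {
    stop("unknown habitat code(s) in grid file: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  nr <- length(rows)
  nc <- lens[1]
  cls <- matrix(match(flat, .class_codes),
                nrow = nr, ncol = nc, byrow = TRUE)
  g <- build_schematic_map(list(), nrow = nr, ncol = nc, habitat = habitat,
                           operational_margin = operational_margin)
  g$class <- cls
  g
}
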