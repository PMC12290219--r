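#' Edge-cost model for the raster graph
#'
#' A friction surface is turned into a weighted graph on its unmasked
#' cells, 8-connected (queen's move). The cost in minutes of the edge
#' between neighbouring cells a and b is the distance `d` between their
#' centers times an average of the two frictions:
#' \describe{
#'   \item{mean_friction}{`d * (f_a + f_b) / 2` - arithmetic mean of the
#'     frictions (default).}
#'   \item{mean_conductance}{`d / ((1/f_a + 1/f_b)/2)` - the average of the
#'     two cells' speeds, as transition-matrix based implementations use.}
#' }
#' `d` is the great-circle distance on geographic grids (so diagonal and
#' high-latitude steps are weighted by true metres, with no separate
#' square-root-of-2 factor) and Euclidean map units on planar grids.
#'
#' @param averaging `"mean_friction"` or `"mean_conductance"`.
#' @param distance `"auto"` (geodesic for geographic grids, planar
#'   otherwise), `"geodesic"`, or `"planar"`.
#' @return An object of class `tt_edge_model`.
#' @export
edge_model <- function(averaging = c("mean_friction", "mean_conductance"),
                       distance = c("auto", "geodesic", "planar")) {
  structure(list(connectivity = 8L,
                 averaging = match.arg(averaging),
                 distance_mode = match.arg(distance)),
            class = "tt_edge_model")
}

resolve_distance_mode <- function(model, grid) {
  if (model$distance_mode != "auto") return(model$distance_mode)
  if (grid$crs == "geographic") "geodesic" else "planar"
}

#' Cost of a single raster-graph edge
#'
#' Mostly of diagnostic interest; [calculate_travel_time()] computes these
#' internally. The two cells must be 8-neighbours and both unmasked.
#'
#' @param surface A `tt_friction`.
#' @param a,b Cells as `c(row, col)` (1-based).
#' @param model An [edge_model()].
#' @return Edge cost in minutes.
#' @export
edge_cost <- function(surface, a, b, model = edge_model()) {
  stopifnot(inherits(surface, "tt_friction"))
  g <- surface$grid
  check_cell(g, a[1], a[2]); check_cell(g, b[1], b[2])
  if (max(abs(a - b)) != 1L) {
    stop("cells (", a[1], ",", a[2], ") and (", b[1], ",", b[2],
         ") are not 8-neighbours", call. = FALSE)
  }
  if (surface$mask[a[1], a[2]] || surface$mask[b[1], b[2]]) {
    stop("no edge: one of the cells is masked (nodata)", call. = FALSE)
  }
  mode <- resolve_distance_mode(model, g)
  ca <- cell_center(g, a[1], a[2]); cb <- cell_center(g, b[1], b[2])
  d <- if (mode == "geodesic") great_circle_distance(ca, cb)
       else sqrt(sum((ca - cb)^2))
  fa <- surface$values[a[1], a[2]]; fb <- surface$values[b[1], b[2]]
  if (model$averaging == "mean_friction") d * (fa + fb) / 2
  else d / ((1 / fa + 1 / fb) / 2)
}

#' Snap point locations to grid cells
#'
#' Validates a coordinate table against a grid: every point must fall
#' inside the grid extent (or be dropped with a warning when
#' `drop_bad_points = TRUE`), and points sharing a cell are collapsed to
#' one source cell. Each retained cell remembers the lowest original point
#' index that snapped to it, which is the label reported by
#' [nearest_source_labels()].
#'
#' @param points A two-column (x, y) data frame or matrix, or a
#'   `tt_source_set`.
#' @param grid A [tt_grid()].
#' @param drop_bad_points Drop out-of-extent points with a warning instead
#'   of erroring.
#' @return A `tt_source_set`: tibble of `row`, `col`, `label`, `x`, `y`.
#' @export
source_set <- function(points, grid, drop_bad_points = FALSE) {
  if (inherits(points, "tt_source_set")) return(points)
  pts <- as.data.frame(points)
  if (ncol(pts) < 2) stop("points need two coordinate columns", call. = FALSE)
  xc <- if ("x" %in% names(pts)) pts$x else pts[[1]]
  yc <- if ("y" %in% names(pts)) pts$y else pts[[2]]
  if (!length(xc)) stop("empty point set: at least one source location is ",
                        "required", call. = FALSE)
  if (!all(is.finite(xc)) || !all(is.finite(yc))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  e <- grid$extent
  out <- xc < e[["xmin"]] | xc > e[["xmax"]] | yc < e[["ymin"]] | yc > e[["ymax"]]
  if (any(out)) {
    if (drop_bad_points) {
      warning(sum(out), " point(s) outside the grid extent dropped",
              call. = FALSE)
      if (all(out)) stop("all points fall outside the grid extent",
                         call. = FALSE)
    } else {
      i <- which(out)[1]
      stop("point ", i, " (", xc[i], ", ", yc[i], ") lies outside the grid ",
           "extent; use drop_bad_points = TRUE to drop and warn instead",
           call. = FALSE)
    }
  }
  keep <- which(!out)
  cells <- point_to_cell(grid, xc[keep], yc[keep])
  first <- !duplicated(cells)
  out <- tibble::tibble(row = cells[first, "row"], col = cells[first, "col"],
                        label = keep[first],
                        x = xc[keep][first], y = yc[keep][first])
  class(out) <- c("tt_source_set", class(out))
  out
}

run_engine <- function(surface, points, model, drop_bad_points) {
  stopifnot(inherits(surface, "tt_friction"))
  if (!inherits(model, "tt_edge_model")) stop("model must be an edge_model()",
                                              call. = FALSE)
  src <- source_set(points, surface$grid, drop_bad_points = drop_bad_points)
  on_mask <- surface$mask[cbind(src$row, src$col)]
  if (all(on_mask)) {
    stop("all source points fall on masked (nodata) cells", call. = FALSE)
  }
  if (any(on_mask)) {
    if (drop_bad_points) {
      warning(sum(on_mask), " source point(s) on masked cells dropped",
              call. = FALSE)
      src <- src[!on_mask, ]
    } else {
      stop(sum(on_mask), " source point(s) fall on masked (nodata) cells; ",
           "use drop_bad_points = TRUE to drop and warn instead",
           call. = FALSE)
    }
  }
  mode <- resolve_distance_mode(model, surface$grid)
  steps <- if (mode == "planar") {
    g <- surface$grid
    list(h = rep(g$resolution_x, g$nrow),
         v = rep(g$resolution_y, max(g$nrow - 1L, 0L)),
         d = rep(sqrt(g$resolution_x^2 + g$resolution_y^2),
                 max(g$nrow - 1L, 0L)))
  } else {
    grid_step_distances(surface$grid)
  }
  fr <- surface$values
  fr[surface$mask] <- 1  # placeholder; masked cells join no edge
  res <- dijkstra_grid(fr, surface$mask, src$row, src$col, src$label,
                       steps$h, steps$v, steps$d,
                       if (model$averaging == "mean_friction") 0L else 1L)
  model$distance_mode <- mode
  list(minutes = res$minutes, labels = res$labels, sources = src,
       model = model)
}

#' Travel time to the nearest source location
#'
#' The core computation: for every unmasked cell, the minimum travel time
#' in minutes to the nearest of the supplied locations, i.e. the
#' shortest-path distance on the 8-connected weighted raster graph (see
#' [edge_model()]) from the cell to any source cell, computed in a single
#' multi-source Dijkstra pass. Source cells have time exactly 0. Unmasked
#' cells in components containing no source - e.g. offshore islands after
#' land masking - get `+Inf`. Masked cells are `NA`. The result is
#' deterministic and independent of source ordering.
#'
#' @param surface A `tt_friction` (see [prepare_friction()],
#'   [synth_friction()], [read_friction_raster()]).
#' @param points Source locations: two-column (x, y) table or
#'   [source_set()].
#' @param model An [edge_model()].
#' @param drop_bad_points Drop (with a warning) points outside the extent
#'   or on masked cells, instead of erroring.
#' @return A `tt_travel_time`: fields `grid`, `minutes` (matrix, `[0, Inf]`
#'   with `NA` at masked cells), `mask`, `edge_model`, `sources`.
#' @examples
#' surf <- synth_friction(1, 3, "uniform", base_value = 0.01)
#' tt <- calculate_travel_time(surf, cbind(x = 1 / 240, y = 1 / 240))
#' tt$minutes  # 0, ~9.27, ~18.53 minutes
#' @export
calculate_travel_time <- function(surface, points, model = edge_model(),
                                  drop_bad_points = FALSE) {
  r <- run_engine(surface, points, model, drop_bad_points)
  structure(list(grid = surface$grid, minutes = r$minutes,
                 mask = surface$mask, edge_model = r$model,
                 sources = r$sources),
            class = "tt_travel_time")
}

#' Label each cell with its nearest source
#'
#' Runs the same multi-source shortest-path computation as
#' [calculate_travel_time()] but reports, for every reachable cell, the
#' index (row number in `points`) of the source achieving the minimum
#' travel time - the catchment allocation. Exact ties go to the lowest
#' source index; unreachable and masked cells are `NA`.
#'
#' @inheritParams calculate_travel_time
#' @return A `tt_source_labels`: fields `grid`, `labels` (integer matrix),
#'   `mask`, `edge_model`, `sources`.
#' @export
nearest_source_labels <- function(surface, points, model = edge_model(),
                                  drop_bad_points = FALSE) {
  r <- run_engine(surface, points, model, drop_bad_points)
  structure(list(grid = surface$grid, labels = r$labels,
                 mask = surface$mask, edge_model = r$model,
                 sources = r$sources),
            class = "tt_source_labels")
}

#' @export
print.tt_travel_time <- function(x, ...) {
  cat("class       : tt_travel_time (minutes)\n")
  print(x$grid)
  v <- x$minutes[!x$mask]
  cat("min value   : ", format(min(v)), "\n", sep = "")
  cat("max value   : ", format(max(v)), "\n", sep = "")
  cat("edge model  : ", x$edge_model$averaging, ", ",
      x$edge_model$distance_mode, ", 8-connected\n", sep = "")
  cat("sources     : ", nrow(x$sources), " cell(s); unreachable cells: ",
      sum(is.infinite(x$minutes), na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' @export
print.tt_source_labels <- function(x, ...) {
  cat("class       : tt_source_labels\n")
  print(x$grid)
  cat("sources     : ", nrow(x$sources), " cell(s)\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.tt_travel_time <- function(x, ...) {
  raster_to_tibble(x$grid, x$minutes, "minutes")
}

#' @exportS3Method tibble::as_tibble
as_tibble.tt_source_labels <- function(x, ...) {
  raster_to_tibble(x$grid, x$labels, "label")
}
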