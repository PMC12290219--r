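#' Friction surface
#'
#' A friction surface assigns every raster cell a traversal cost in minutes
#' per metre (the reciprocal of speed). Masked cells (nodata) are
#' impassable: they take part in no graph edge. Every unmasked value must be
#' finite and strictly positive.
#'
#' Values above 10 min/m (slower than 6 m/h) almost always indicate a unit
#' mistake (e.g. minutes per kilometre read as minutes per metre) and
#' trigger a warning; the values are never converted.
#'
#' @param values Numeric `nrow x ncol` matrix of friction, minutes per
#'   metre. Non-finite entries are treated as nodata.
#' @param grid The [tt_grid()] the values sit on; `dim(values)` must equal
#'   `c(grid$nrow, grid$ncol)`.
#' @param mask Optional logical matrix, `TRUE` = nodata. Combined with
#'   non-finite `values` entries.
#' @return An object of class `tt_friction` with fields `grid`, `values`
#'   (masked cells are `NA`) and `mask`.
#' @export
friction_surface <- function(values, grid, mask = NULL) {
  stopifnot(inherits(grid, "tt_grid"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(dim(values) == c(grid$nrow, grid$ncol))) {
    stop("friction values are ", nrow(values), " x ", ncol(values),
         " but the grid is ", grid$nrow, " x ", grid$ncol, call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, grid$nrow, grid$ncol)
  } else {
    mask <- as.matrix(mask)
    stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
    mask[is.na(mask)] <- TRUE
  }
  mask <- mask | !is.finite(values)
  n_bad <- sum(values[!mask] <= 0)
  if (n_bad > 0) {
    stop("friction surface has ", n_bad, " unmasked cell(s) with ",
         "non-positive values; friction must be strictly positive (min/m)",
         call. = FALSE)
  }
  if (any(values[!mask] > 10)) {
    warning("friction values exceed 10 minutes per metre; check that the ",
            "surface really is in minutes per metre", call. = FALSE)
  }
  values[mask] <- NA_real_
  structure(list(grid = grid, values = values, mask = mask),
            class = "tt_friction")
}

#' @export
print.tt_friction <- function(x, ...) {
  cat("class       : tt_friction (minutes per metre)\n")
  print(x$grid)
  v <- x$values[!x$mask]
  if (length(v)) {
    cat(sprintf("min value   : %.8f\n", min(v)))
    cat(sprintf("max value   : %.8f\n", max(v)))
  } else cat("all cells masked\n")
  cat("nodata cells: ", sum(x$mask), " of ", length(x$mask), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.tt_friction <- function(x, ...) {
  raster_to_tibble(x$grid, x$values, "friction")
}

raster_to_tibble <- function(grid, values, name) {
  idx <- expand.grid(row = seq_len(grid$nrow), col = seq_len(grid$ncol))
  ctr <- cell_center(grid, idx$row, idx$col)
  out <- tibble::tibble(row = idx$row, col = idx$col,
                        x = ctr[, "x"], y = ctr[, "y"],
                        value = as.vector(values))
  names(out)[names(out) == "value"] <- name
  out
}

#' The named global friction surfaces
#'
#' The two 2020 global surfaces at 30 arc-second resolution that a fetch
#' adapter can serve: walking-only (`"walk2020"`) and motorised transport
#' (`"motor2020"`).
#' @return Character vector of valid surface names.
#' @export
surface_names <- function() c("walk2020", "motor2020")

#' Configure the fetch adapter for named surfaces
#'
#' Named global surfaces are served through a pluggable adapter so that all
#' computation can run offline: the adapter is any
#' `function(name, grid) -> tt_friction` returning the named surface on
#' exactly the requested (snapped) grid. No adapter ships enabled by
#' default; requesting a named surface without one raises an "offline"
#' error.
#'
#' @param adapter A function, or `NULL` to unset.
#' @return The previously configured adapter, invisibly.
#' @export
set_fetch_adapter <- function(adapter) {
  stopifnot(is.null(adapter) || is.function(adapter))
  old <- getOption("timeraster.fetch_adapter")
  options(timeraster.fetch_adapter = adapter)
  invisible(old)
}

#' Fetch a named global friction surface
#'
#' Snaps the requested extent to the global 1/120-degree lattice, then asks
#' the configured fetch adapter for the surface on that grid. When
#' `cache_dir` is given, results are cached on disk as GeoTIFF keyed by
#' (name, snapped extent); a repeated call is served from the cache without
#' invoking the adapter.
#'
#' @param name One of [surface_names()].
#' @param extent Requested extent ([tt_extent()] or numeric(4)).
#' @param adapter Fetch adapter; defaults to the one configured with
#'   [set_fetch_adapter()].
#' @param cache_dir Optional directory for the on-disk cache.
#' @return A `tt_friction` on the snapped grid.
#' @export
fetch_named_surface <- function(name, extent,
                                adapter = getOption("timeraster.fetch_adapter"),
                                cache_dir = NULL) {
  name <- match.arg(name, surface_names())
  grid <- snap_extent(as_tt_extent(extent))
  if (!is.null(cache_dir)) {
    key <- sprintf("%s_%s.tif", name,
                   paste(sprintf("%.10f", unclass(grid$extent)), collapse = "_"))
    cache_file <- file.path(cache_dir, key)
    if (file.exists(cache_file)) {
      return(read_friction_raster(cache_file))
    }
  }
  if (is.null(adapter)) {
    stop("offline: no fetch adapter is configured for named surface '", name,
         "'; supply your own friction raster, or set_fetch_adapter()",
         call. = FALSE)
  }
  surf <- tryCatch(adapter(name, grid), error = function(e) {
    stop("fetching named surface '", name, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  if (!inherits(surf, "tt_friction")) {
    stop("fetch adapter must return a tt_friction", call. = FALSE)
  }
  if (!grids_equal(surf$grid, grid)) {
    stop("fetch adapter returned a surface on the wrong grid", call. = FALSE)
  }
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    write_friction_raster(surf, cache_file)
  }
  surf
}

#' Prepare a friction surface for an area of interest
#'
#' The first step of the travel-time workflow. Either fetches a named
#' global surface for the area of interest (grid = the requested extent
#' snapped to the global 1/120-degree lattice), or crops a user-supplied
#' raster to the area of interest on the raster's own grid - never
#' resampled, so every output value equals an input value. Optionally masks
#' cells outside a polygon.
#'
#' @param source A surface name (see [surface_names()]), a `tt_friction`,
#'   or a path to a single-band GeoTIFF.
#' @param aoi Area of interest: a [tt_extent()], numeric(4)
#'   `c(xmin, xmax, ymin, ymax)`, or a polygon (its bounding box is used).
#' @param mask Optional polygon ([read_polygon()] result or GeoJSON path);
#'   cells whose center falls outside it become nodata.
#' @param adapter,cache_dir Passed to [fetch_named_surface()] for named
#'   sources.
#' @return A `tt_friction`.
#' @examples
#' surf <- synth_friction(10, 10, "gradient")
#' cropped <- prepare_friction(surf, c(0.02, 0.05, 0.02, 0.05))
#' cropped$grid$nrow
#' @export
prepare_friction <- function(source, aoi, mask = NULL,
                             adapter = getOption("timeraster.fetch_adapter"),
                             cache_dir = NULL) {
  if (is.character(source) && length(source) == 1 &&
      source %in% surface_names()) {
    surf <- fetch_named_surface(source, as_tt_extent(aoi), adapter = adapter,
                                cache_dir = cache_dir)
  } else {
    surf <- if (is.character(source)) read_friction_raster(source)
    else if (inherits(source, "tt_friction")) source
    else stop("source must be a surface name, a tt_friction, or a raster path",
              call. = FALSE)
    surf <- crop_to_extent(surf, as_tt_extent(aoi))
  }
  if (!is.null(mask)) surf <- mask_surface(surf, mask)
  surf
}

# Crop a surface to the cell range covered by an extent, on its own grid.
crop_to_extent <- function(surface, aoi) {
  g <- surface$grid
  e <- g$extent
  if (aoi[["xmax"]] <= e[["xmin"]] || aoi[["xmin"]] >= e[["xmax"]] ||
      aoi[["ymax"]] <= e[["ymin"]] || aoi[["ymin"]] >= e[["ymax"]]) {
    stop("area of interest does not overlap the raster extent", call. = FALSE)
  }
  eps <- 1e-6  # in cell units: tolerates coordinates printed to ~10 decimals
  c0 <- max(1L, as.integer(floor((aoi[["xmin"]] - e[["xmin"]]) / g$resolution_x + eps)) + 1L)
  c1 <- min(g$ncol, as.integer(ceiling((aoi[["xmax"]] - e[["xmin"]]) / g$resolution_x - eps)))
  r0 <- max(1L, as.integer(floor((e[["ymax"]] - aoi[["ymax"]]) / g$resolution_y + eps)) + 1L)
  r1 <- min(g$nrow, as.integer(ceiling((e[["ymax"]] - aoi[["ymin"]]) / g$resolution_y - eps)))
  sub_vals <- surface$values[r0:r1, c0:c1, drop = FALSE]
  sub_mask <- surface$mask[r0:r1, c0:c1, drop = FALSE]
  if (all(sub_mask)) {
    stop("all ", length(sub_mask), " cells in the area of interest are nodata",
         call. = FALSE)
  }
  ext <- tt_extent(
    e[["xmin"]] + (c0 - 1L) * g$resolution_x,
    e[["xmin"]] + c1 * g$resolution_x,
    e[["ymax"]] - r1 * g$resolution_y,
    e[["ymax"]] - (r0 - 1L) * g$resolution_y,
    crs = g$crs
  )
  friction_surface(sub_vals, tt_grid(ext, g$resolution_x, g$resolution_y),
                   mask = sub_mask)
}

#' Mask a friction surface by a polygon
#'
#' Cells whose center falls outside the polygon become nodata (impassable);
#' all other cells are unchanged, so masking is idempotent and the masked
#' set can only grow under successive masks. Whole cells are kept or
#' dropped - there is no fractional coverage - matching the all-or-nothing
#' behaviour of cells on offshore islands, which survive land masking as
#' unmasked cells disconnected from the mainland.
#'
#' @param surface A `tt_friction`.
#' @param polygon A `tt_polygon` (see [read_polygon()]), a ring matrix, or a
#'   GeoJSON file path. Must be in the surface's CRS.
#' @return The masked `tt_friction`.
#' @export
mask_surface <- function(surface, polygon) {
  stopifnot(inherits(surface, "tt_friction"))
  polygon <- as_tt_polygon(polygon)
  g <- surface$grid
  idx <- expand.grid(row = seq_len(g$nrow), col = seq_len(g$ncol))
  ctr <- cell_center(g, idx$row, idx$col)
  inside <- points_in_polygon(polygon, ctr)
  if (!any(inside)) {
    stop("polygon is disjoint from the surface extent: no cell center falls ",
         "inside it, the masked surface would be empty", call. = FALSE)
  }
  new_mask <- surface$mask
  new_mask[cbind(idx$row, idx$col)[!inside, , drop = FALSE]] <- TRUE
  friction_surface(surface$values, g, mask = new_mask)
}

#' Generate a synthetic friction surface
#'
#' Deterministic fixture surfaces for tests, documentation and benchmarks.
#' Patterns:
#' \describe{
#'   \item{uniform}{every cell exactly `base_value`.}
#'   \item{gradient}{west-to-east linear ramp from `base_value` to
#'     `5 * base_value`.}
#'   \item{random}{i.i.d. log-uniform draws in
#'     `[base_value, 5 * base_value]`, reproducible for a given `seed`.}
#'   \item{corridor_with_barrier}{uniform surface split by one fully masked
#'     column into two disconnected components - exercises the infinite
#'     travel time contract.}
#' }
#'
#' @param nrow,ncol Grid dimensions (>= 1).
#' @param pattern One of the patterns above.
#' @param base_value Base friction, minutes per metre; default 0.012, the
#'   minimum walking friction of the 2020 global surface (~5 km/h).
#' @param seed Integer seed for `pattern = "random"`; the caller's RNG
#'   state is left untouched.
#' @param extent Grid extent; defaults to `nrow x ncol` cells of
#'   `resolution` anchored at (0, 0).
#' @param resolution Cell size, default 1/120 degree.
#' @param crs `"geographic"` or `"planar"`.
#' @return A `tt_friction`.
#' @examples
#' synth_friction(5, 5, "corridor_with_barrier")
#' @export
synth_friction <- function(nrow, ncol,
                           pattern = c("uniform", "gradient", "random",
                                       "corridor_with_barrier"),
                           base_value = 0.012, seed = NULL, extent = NULL,
                           resolution = 1 / 120,
                           crs = c("geographic", "planar")) {
  pattern <- match.arg(pattern)
  crs <- match.arg(crs)
  stopifnot(nrow >= 1, ncol >= 1, base_value > 0)
  if (is.null(extent)) {
    extent <- tt_extent(0, ncol * resolution, 0, nrow * resolution, crs = crs)
  } else {
    extent <- as_tt_extent(extent, crs = crs)
  }
  grid <- tt_grid(extent, resolution, resolution)
  stopifnot(grid$nrow == nrow, grid$ncol == ncol)
  mask <- NULL
  if (pattern == "uniform") {
    vals <- matrix(base_value, nrow, ncol)
  } else if (pattern == "gradient") {
    ramp <- if (ncol == 1) base_value else
      base_value * (1 + 4 * (seq_len(ncol) - 1) / (ncol - 1))
    vals <- matrix(ramp, nrow, ncol, byrow = TRUE)
  } else if (pattern == "random") {
    if (is.null(seed)) stop("pattern 'random' requires a seed", call. = FALSE)
    vals <- with_local_seed(seed, {
      matrix(exp(stats::runif(nrow * ncol, log(base_value),
                              log(5 * base_value))), nrow, ncol)
    })
  } else { # corridor_with_barrier
    if (ncol < 3) stop("corridor_with_barrier needs ncol >= 3", call. = FALSE)
    vals <- matrix(base_value, nrow, ncol)
    mask <- matrix(FALSE, nrow, ncol)
    mask[, floor(ncol / 2) + 1L] <- TRUE
  }
  friction_surface(vals, grid, mask = mask)
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
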