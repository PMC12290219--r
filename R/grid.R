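#' Geographic extent
#'
#' An axis-aligned bounding box. In geographic mode coordinates are decimal
#' degrees (WGS84 lon/lat); in planar mode they are map units of a projected
#' grid. Extents that would cross the antimeridian cannot be represented
#' (xmin < xmax is required) and are therefore rejected.
#'
#' @param xmin,xmax,ymin,ymax Bounds. `xmin < xmax`, `ymin < ymax`.
#' @param crs Either `"geographic"` (default; bounds checked against
#'   \[-180, 180\] x \[-90, 90\]) or `"planar"`.
#' @return An object of class `tt_extent`: a named numeric vector with a
#'   `crs` attribute.
#' @examples
#' tt_extent(103.6091, 104.0858, 1.1664, 1.4714)
#' @export
tt_extent <- function(xmin, xmax, ymin, ymax, crs = c("geographic", "planar")) {
  crs <- match.arg(crs)
  vals <- c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  if (anyNA(vals) || !all(is.finite(vals))) {
    stop("extent bounds must be finite numbers", call. = FALSE)
  }
  if (xmin >= xmax) {
    stop("invalid extent: xmin (", xmin, ") must be < xmax (", xmax,
         "); antimeridian-crossing extents are not supported", call. = FALSE)
  }
  if (ymin >= ymax) {
    stop("invalid extent: ymin (", ymin, ") must be < ymax (", ymax, ")",
         call. = FALSE)
  }
  if (crs == "geographic") {
    if (xmin < -180 || xmax > 180 || ymin < -90 || ymax > 90) {
      stop("geographic extent out of range: longitudes must lie in [-180, 180]",
           " and latitudes in [-90, 90]", call. = FALSE)
    }
  }
  structure(vals, crs = crs, class = "tt_extent")
}

as_tt_extent <- function(x, crs = "geographic") {
  if (inherits(x, "tt_extent")) return(x)
  if (inherits(x, "tt_polygon")) return(polygon_bbox(x))
  if (is.numeric(x) && length(x) == 4) {
    return(tt_extent(x[[1]], x[[2]], x[[3]], x[[4]], crs = crs))
  }
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as an extent; supply tt_extent(), numeric(4) (xmin, xmax, ymin, ymax), ",
       "or a polygon", call. = FALSE)
}

#' @export
print.tt_extent <- function(x, ...) {
  cat("extent      : ", paste(format(unclass(x), trim = TRUE), collapse = ", "),
      " (xmin, xmax, ymin, ymax) [", attr(x, "crs"), "]\n", sep = "")
  invisible(x)
}

#' Raster grid specification
#'
#' Describes an axis-aligned, north-up raster grid: its extent, cell
#' resolution and dimensions. Row 1 is the northernmost row; column 1 the
#' westernmost column.
#'
#' @param extent A [tt_extent()] whose bounds are exact multiples of the
#'   resolution apart.
#' @param resolution_x,resolution_y Cell size in degrees (or map units).
#' @return An object of class `tt_grid` with fields `extent`,
#'   `resolution_x`, `resolution_y`, `nrow`, `ncol`, `crs`.
#' @seealso [snap_extent()] to construct a grid from an arbitrary extent.
#' @export
tt_grid <- function(extent, resolution_x, resolution_y = resolution_x) {
  extent <- as_tt_extent(extent)
  if (resolution_x <= 0 || resolution_y <= 0) {
    stop("resolution must be strictly positive", call. = FALSE)
  }
  width <- extent[["xmax"]] - extent[["xmin"]]
  height <- extent[["ymax"]] - extent[["ymin"]]
  nc <- round(width / resolution_x)
  nr <- round(height / resolution_y)
  if (nc < 1 || abs(nc * resolution_x - width) > 1e-9 * max(1, abs(width))) {
    stop("extent width is not an integer multiple of resolution_x", call. = FALSE)
  }
  if (nr < 1 || abs(nr * resolution_y - height) > 1e-9 * max(1, abs(height))) {
    stop("extent height is not an integer multiple of resolution_y", call. = FALSE)
  }
  structure(
    list(extent = extent, resolution_x = resolution_x,
         resolution_y = resolution_y, nrow = as.integer(nr),
         ncol = as.integer(nc), crs = attr(extent, "crs")),
    class = "tt_grid"
  )
}

#' @export
print.tt_grid <- function(x, ...) {
  cat("dimensions  : ", x$nrow, ", ", x$ncol, " (nrow, ncol)\n", sep = "")
  cat("resolution  : ", format(x$resolution_x), ", ", format(x$resolution_y),
      " (x, y)\n", sep = "")
  print(x$extent)
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol && a$crs == b$crs &&
    all(abs(unclass(a$extent) - unclass(b$extent)) <= tol) &&
    abs(a$resolution_x - b$resolution_x) <= tol &&
    abs(a$resolution_y - b$resolution_y) <= tol
}

#' Snap an extent to the global raster lattice
#'
#' Moves each bound of a requested extent to the nearest line of the global
#' lattice of `resolution`-sized cells anchored at (-180, -90) (or at a
#' caller-supplied anchor). Ties round toward +infinity. This reproduces the
#' grid registration of the global 30 arc-second (1/120 degree) friction
#' surfaces: a requested Singapore bounding box of
#' (103.6091, 104.0858, 1.1664, 1.4714) snaps to
#' (103.608333, 104.083333, 1.166667, 1.475), a 37 x 57 grid.
#'
#' Snapping an already-aligned extent is the identity, and the operation is
#' idempotent. A requested extent narrower than half a cell on some axis can
#' snap to zero cells; that is rejected with an error naming the axis.
#'
#' @param requested A [tt_extent()] (or numeric `c(xmin, xmax, ymin, ymax)`).
#' @param resolution Lattice cell size, degrees (or map units); default the
#'   30 arc-second global lattice, 1/120 degree.
#' @param anchor Lattice origin, default `c(-180, -90)`.
#' @return A [tt_grid()] covering the snapped extent.
#' @examples
#' snap_extent(tt_extent(103.6091, 104.0858, 1.1664, 1.4714))
#' @export
snap_extent <- function(requested, resolution = 1 / 120,
                        anchor = c(-180, -90)) {
  requested <- as_tt_extent(requested)
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  # nearest lattice line; floor(k + 0.5) rounds exact ties toward +Inf
  snap1 <- function(v, a) a + floor((v - a) / resolution + 0.5) * resolution
  xmin <- snap1(requested[["xmin"]], anchor[[1]])
  xmax <- snap1(requested[["xmax"]], anchor[[1]])
  ymin <- snap1(requested[["ymin"]], anchor[[2]])
  ymax <- snap1(requested[["ymax"]], anchor[[2]])
  if (xmax - xmin < resolution / 2) {
    stop("snapped extent is degenerate on the x axis (zero columns): ",
         "requested [", requested[["xmin"]], ", ", requested[["xmax"]], "]",
         call. = FALSE)
  }
  if (ymax - ymin < resolution / 2) {
    stop("snapped extent is degenerate on the y axis (zero rows): ",
         "requested [", requested[["ymin"]], ", ", requested[["ymax"]], "]",
         call. = FALSE)
  }
  ext <- tt_extent(xmin, xmax, ymin, ymax, crs = attr(requested, "crs"))
  tt_grid(ext, resolution, resolution)
}

check_cell <- function(grid, row, col) {
  bad <- row < 1L | row > grid$nrow | col < 1L | col > grid$ncol
  if (any(bad)) {
    i <- which(bad)[1]
    stop("cell (", row[i], ", ", col[i], ") is outside the ", grid$nrow, " x ",
         grid$ncol, " grid", call. = FALSE)
  }
}

#' Coordinates of a cell center
#'
#' Rows and columns are 1-based; row 1 is the northernmost row.
#'
#' @param grid A [tt_grid()].
#' @param row,col Cell indices (vectors allowed, recycled together).
#' @return A two-column matrix of (x, y) center coordinates.
#' @export
cell_center <- function(grid, row, col) {
  stopifnot(inherits(grid, "tt_grid"))
  row <- as.integer(row); col <- as.integer(col)
  check_cell(grid, row, col)
  cbind(
    x = grid$extent[["xmin"]] + (col - 0.5) * grid$resolution_x,
    y = grid$extent[["ymax"]] - (row - 0.5) * grid$resolution_y
  )
}

#' Locate the cell containing a point
#'
#' Cells are half-open: a point on an interior grid line belongs to the cell
#' to its east (in x) or south (in y); points exactly on the extent's far
#' edges (xmax, ymin) belong to the last column / row, so no point inside
#' the closed extent is orphaned.
#'
#' @param grid A [tt_grid()].
#' @param x,y Point coordinates (vectors allowed).
#' @return A two-column integer matrix of (row, col), 1-based.
#' @export
point_to_cell <- function(grid, x, y) {
  stopifnot(inherits(grid, "tt_grid"))
  e <- grid$extent
  out <- x < e[["xmin"]] | x > e[["xmax"]] | y < e[["ymin"]] | y > e[["ymax"]]
  if (any(out)) {
    i <- which(out)[1]
    stop("point (", x[i], ", ", y[i], ") lies outside the grid extent (",
         paste(format(unclass(e), trim = TRUE), collapse = ", "), ")",
         call. = FALSE)
  }
  col <- pmin(grid$ncol, floor((x - e[["xmin"]]) / grid$resolution_x) + 1L)
  row <- pmin(grid$nrow, floor((e[["ymax"]] - y) / grid$resolution_y) + 1L)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6,371,008.8 m (IUGG mean Earth
#' radius), used to weight raster-graph edges so that travel minutes equal
#' friction (minutes per metre) times metres traversed.
#'
#' @param p1,p2 Two-column (lon, lat) matrices or length-2 vectors, degrees.
#' @return Distance(s) in metres.
#' @examples
#' great_circle_distance(c(0, 0), c(1 / 120, 0)) # one 30 arc-sec cell, ~926.6 m
#' @export
great_circle_distance <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371008.8)
}

# Per-row step lengths between 8-neighbour cell centers. For geographic
# grids the horizontal step varies with latitude (cos shrinkage) and the
# diagonal with the row pair; the vertical step is constant on the sphere.
grid_step_distances <- function(grid) {
  nr <- grid$nrow
  if (grid$crs == "planar") {
    rx <- grid$resolution_x; ry <- grid$resolution_y
    return(list(h = rep(rx, nr), v = rep(ry, max(nr - 1L, 0L)),
                d = rep(sqrt(rx^2 + ry^2), max(nr - 1L, 0L))))
  }
  lat <- grid$extent[["ymax"]] - (seq_len(nr) - 0.5) * grid$resolution_y
  lon0 <- grid$extent[["xmin"]] + 0.5 * grid$resolution_x
  lon1 <- lon0 + grid$resolution_x
  h <- great_circle_distance(cbind(lon0, lat), cbind(lon1, lat))
  if (nr > 1L) {
    v <- great_circle_distance(cbind(lon0, lat[-nr]), cbind(lon0, lat[-1]))
    d <- great_circle_distance(cbind(lon0, lat[-nr]), cbind(lon1, lat[-1]))
  } else {
    v <- numeric(0); d <- numeric(0)
  }
  list(h = h, v = v, d = d)
}
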