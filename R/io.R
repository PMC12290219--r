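#' Read a friction surface from a GeoTIFF
#'
#' The file must be a single-band, axis-aligned, georeferenced raster. The
#' file's nodata sentinel and any non-finite cells become the surface mask;
#' remaining values are validated as strictly positive friction in minutes
#' per metre.
#'
#' @param path Path to a single-band GeoTIFF.
#' @return A [friction_surface()].
#' @export
read_friction_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  r <- geotiff_read(path)
  vals <- r$values
  mask <- !is.finite(vals)
  if (!is.null(r$nodata) && is.finite(r$nodata)) {
    mask <- mask | (vals == r$nodata)
  }
  friction_surface(vals, r$grid, mask = mask)
}

#' Write a friction surface to GeoTIFF
#'
#' Values are stored at native double precision; masked cells are written
#' as the nodata sentinel.
#'
#' @param surface A `tt_friction`.
#' @param path Output path.
#' @param nodata Nodata sentinel to write; default -9999.
#' @return `path`, invisibly.
#' @export
write_friction_raster <- function(surface, path, nodata = -9999) {
  stopifnot(inherits(surface, "tt_friction"))
  meta <- jsonlite::toJSON(list(type = "friction", units = "minutes_per_metre",
                                n_masked = sum(surface$mask)),
                           auto_unbox = TRUE)
  geotiff_write(path, surface$values, surface$grid, nodata = nodata,
                dtype = "float64", description = as.character(meta))
  invisible(path)
}

#' Write a travel-time raster to GeoTIFF
#'
#' Written as float32 (minutes need fewer than 7 significant digits).
#' GeoTIFF consumers handle IEEE infinity inconsistently, so both infinite
#' (unreachable) and masked cells are written as the nodata sentinel; the
#' counts of each, and the edge model used, are preserved in the file's
#' metadata tag. In memory the raster keeps true `+Inf` for unreachable
#' cells and `NA` for masked ones.
#'
#' @param raster A `tt_travel_time` from [calculate_travel_time()].
#' @param path Output path.
#' @param nodata Nodata sentinel; default -9999.
#' @return `path`, invisibly.
#' @export
write_travel_time <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "tt_travel_time"))
  meta <- jsonlite::toJSON(
    list(type = "travel_time", units = "minutes",
         n_infinite = sum(is.infinite(raster$minutes)),
         n_masked = sum(raster$mask),
         edge_model = unclass(raster$edge_model)),
    auto_unbox = TRUE)
  geotiff_write(path, raster$minutes, raster$grid, nodata = nodata,
                dtype = "float32", description = as.character(meta))
  invisible(path)
}

#' Read back a travel-time GeoTIFF
#'
#' Cells equal to the nodata sentinel (whether they were unreachable or
#' masked when written) come back as `NA`; the metadata tag, with the
#' original infinite/masked counts and edge model, is attached as the
#' `"metadata"` attribute.
#'
#' @param path Path written by [write_travel_time()].
#' @return Numeric matrix of minutes with attributes `grid` and `metadata`.
#' @export
read_travel_time <- function(path) {
  r <- geotiff_read(path)
  vals <- r$values
  if (!is.null(r$nodata)) vals[vals == r$nodata] <- NA_real_
  meta <- if (!is.null(r$description)) {
    tryCatch(jsonlite::fromJSON(r$description), error = function(e) r$description)
  }
  structure(vals, grid = r$grid, metadata = meta)
}

#' Read point locations
#'
#' Reads a two-column coordinate table from a headered CSV (comma
#' separator, `.` decimal point) or from GeoJSON Point/MultiPoint features.
#' File order and count are preserved.
#'
#' @param path CSV or GeoJSON file. GeoJSON is detected by a `.geojson` /
#'   `.json` extension.
#' @param x_col,y_col CSV column names holding x (longitude) and y
#'   (latitude); defaults `"x"` and `"y"`.
#' @return A tibble with numeric columns `x` and `y`.
#' @export
read_points <- function(path, x_col = "x", y_col = "y") {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    return(read_points_geojson(path))
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse '", path, "' as CSV: ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0) {
    stop("'", path, "' contains no points", call. = FALSE)
  }
  for (col in c(x_col, y_col)) {
    if (!col %in% names(df)) {
      stop("'", path, "' has no column '", col, "' (columns: ",
           paste(names(df), collapse = ", "), ")", call. = FALSE)
    }
  }
  x <- df[[x_col]]; y <- df[[y_col]]
  if (!is.numeric(x)) x <- suppressWarnings(as.numeric(x))
  if (!is.numeric(y)) y <- suppressWarnings(as.numeric(y))
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    stop("non-numeric or missing coordinate in '", path, "' at row ",
         which(bad)[1], call. = FALSE)
  }
  tibble::tibble(x = x, y = y)
}

read_points_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pts <- list()
  collect <- function(g) {
    if (is.null(g$type)) return()
    if (g$type == "Point") {
      pts[[length(pts) + 1]] <<- c(g$coordinates[[1]], g$coordinates[[2]])
    } else if (g$type == "MultiPoint") {
      for (p in g$coordinates) pts[[length(pts) + 1]] <<- c(p[[1]], p[[2]])
    } else if (g$type == "Feature") collect(g$geometry)
    else if (g$type == "FeatureCollection") for (f in g$features) collect(f)
  }
  collect(gj)
  if (!length(pts)) {
    stop("'", path, "' contains no Point features", call. = FALSE)
  }
  m <- do.call(rbind, pts)
  tibble::tibble(x = m[, 1], y = m[, 2])
}
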