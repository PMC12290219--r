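#' Read a polygon from GeoJSON
#'
#' Reads the first Polygon or MultiPolygon feature (or bare geometry) of a
#' GeoJSON file. All rings of all parts are kept; membership is decided by
#' the even-odd rule, so holes and multipart outlines behave as expected.
#'
#' @param path Path to a GeoJSON file.
#' @return An object of class `tt_polygon`: a list of two-column (x, y)
#'   ring matrices.
#' @export
read_polygon <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geom <- geojson_first_geometry(gj, c("Polygon", "MultiPolygon"))
  if (is.null(geom)) {
    stop("no Polygon or MultiPolygon geometry found in '", path, "'",
         call. = FALSE)
  }
  rings <- if (geom$type == "Polygon") geom$coordinates
           else do.call(c, geom$coordinates)
  rings <- lapply(rings, function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    m
  })
  structure(rings, class = "tt_polygon")
}

geojson_first_geometry <- function(gj, types) {
  if (is.null(gj$type)) return(NULL)
  if (gj$type %in% types) return(gj)
  if (gj$type == "Feature") return(geojson_first_geometry(gj$geometry, types))
  if (gj$type == "FeatureCollection") {
    for (f in gj$features) {
      g <- geojson_first_geometry(f, types)
      if (!is.null(g)) return(g)
    }
  }
  NULL
}

as_tt_polygon <- function(x) {
  if (inherits(x, "tt_polygon")) return(x)
  if (is.character(x) && length(x) == 1) return(read_polygon(x))
  if (is.matrix(x) && ncol(x) == 2) {
    return(structure(list(x), class = "tt_polygon"))
  }
  if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) {
    return(structure(x, class = "tt_polygon"))
  }
  stop("cannot interpret object as a polygon; supply a tt_polygon, a ",
       "two-column ring matrix, or a GeoJSON path", call. = FALSE)
}

polygon_bbox <- function(poly, crs = "geographic") {
  xy <- do.call(rbind, unclass(poly))
  tt_extent(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]), crs = crs)
}

# Even-odd point-in-polygon over all rings, NA rows separating rings as
# mgcv::in.out expects.
points_in_polygon <- function(poly, pts) {
  rings <- lapply(unclass(poly), function(r) {
    # in.out wants closed loops; close if needed
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    r
  })
  sep <- matrix(NA_real_, 1, 2)
  bnd <- do.call(rbind, Reduce(function(a, b) c(a, list(sep), list(b)),
                               rings[-1], list(rings[[1]])))
  mgcv::in.out(bnd, as.matrix(pts))
}
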