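# Minimal single-band GeoTIFF codec.
#
# Scope: classic (non-Big) TIFF, single band, uncompressed, strip-based,
# float32/float64 (read also accepts 8/16/32-bit integer samples),
# axis-aligned georeferencing via ModelPixelScale + ModelTiepoint, CRS kind
# via a GeoKeyDirectory (GTModelType 2 = geographic/WGS84, 1 = projected),
# nodata via the GDAL_NODATA ASCII tag, free-form metadata via
# ImageDescription. Write is always little-endian; read handles both byte
# orders. This covers everything the package itself writes plus plain
# exports from mainstream GIS tools; tiled or compressed files are
# rejected with an explanatory error.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

geotiff_write <- function(path, values, grid, nodata = -9999,
                          dtype = c("float32", "float64"),
                          description = NULL) {
  dtype <- match.arg(dtype)
  stopifnot(inherits(grid, "tt_grid"),
            all(dim(values) == c(grid$nrow, grid$ncol)))
  nr <- grid$nrow; nc <- grid$ncol
  px_size <- if (dtype == "float32") 4L else 8L
  pix <- as.vector(t(values))          # TIFF is row-major, row 1 = top
  pix[!is.finite(pix)] <- nodata
  if (dtype == "float32") {
    # round-trip through float32 so in-memory comparisons match the file
    pix_raw <- writeBin(pix, raw(), size = 4L, endian = "little")
  } else {
    pix_raw <- writeBin(pix, raw(), size = 8L, endian = "little")
  }

  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8L, endian = "little")

  geokeys <- rbind(
    c(1L, 1L, 0L, if (grid$crs == "geographic") 3L else 2L), # header
    c(1024L, 0L, 1L, if (grid$crs == "geographic") 2L else 1L),
    c(1025L, 0L, 1L, 1L),                                    # PixelIsArea
    if (grid$crs == "geographic") c(2048L, 0L, 1L, 4326L)
  )
  nodata_str <- c(charToRaw(format(nodata, scientific = FALSE)), as.raw(0L))

  # tag, type, count, payload (raw); payload <= 4 bytes is stored inline
  entries <- list(
    list(256L, 4L, 1L, u32(nc)),
    list(257L, 4L, 1L, u32(nr)),
    list(258L, 3L, 1L, u16(px_size * 8L)),
    list(259L, 3L, 1L, u16(1L)),
    list(262L, 3L, 1L, u16(1L)),
    list(273L, 4L, 1L, NULL),            # strip offset, patched below
    list(277L, 3L, 1L, u16(1L)),
    list(278L, 4L, 1L, u32(nr)),
    list(279L, 4L, 1L, u32(length(pix_raw))),
    list(284L, 3L, 1L, u16(1L)),
    list(339L, 3L, 1L, u16(3L)),
    list(33550L, 12L, 3L, f64(c(grid$resolution_x, grid$resolution_y, 0))),
    list(33922L, 12L, 6L, f64(c(0, 0, 0, grid$extent[["xmin"]],
                                grid$extent[["ymax"]], 0))),
    list(34735L, 3L, length(t(geokeys)), u16(as.vector(t(geokeys)))),
    list(42113L, 2L, length(nodata_str), nodata_str)
  )
  if (!is.null(description)) {
    d <- c(charToRaw(description), as.raw(0L))
    entries <- append(entries, list(list(270L, 2L, length(d), d)), after = 5)
  }
  entries <- entries[order(vapply(entries, `[[`, integer(1), 1L))]

  n <- length(entries)
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n * 12L + 4L  # external area starts here
  ext <- raw(0)
  entry_raw <- raw(0)
  strip_entry_pos <- NA_integer_
  for (i in seq_len(n)) {
    e <- entries[[i]]
    payload <- e[[4]]
    if (e[[1]] == 273L) {
      strip_entry_pos <- length(entry_raw) + 9L  # value field, 1-based
      payload <- u32(0L)                          # patched after layout
    }
    val_field <- if (length(payload) <= 4L) {
      c(payload, raw(4L - length(payload)))
    } else {
      off <- data_offset + length(ext)
      if (off %% 2L == 1L) { ext <- c(ext, raw(1)); off <- off + 1L }
      ext <- c(ext, payload)
      u32(off)
    }
    entry_raw <- c(entry_raw, u16(e[[1]]), u16(e[[2]]), u32(e[[3]]), val_field)
  }
  pix_offset <- data_offset + length(ext)
  if (pix_offset %% 2L == 1L) { ext <- c(ext, raw(1)); pix_offset <- pix_offset + 1L }
  entry_raw[strip_entry_pos:(strip_entry_pos + 3L)] <- u32(pix_offset)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16(42L), u32(ifd_offset)), con)
  writeBin(c(u16(n), entry_raw, u32(0L), ext, pix_raw), con)
  invisible(path)
}

geotiff_read <- function(path) {
  raw_all <- readBin(path, raw(), n = file.size(path))
  if (length(raw_all) < 8) stop("'", path, "' is not a TIFF file", call. = FALSE)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("'", path, "' is not a TIFF file (bad byte order mark)",
                        call. = FALSE))
  rd <- function(offset, n, size, what = "integer", signed = TRUE) {
    readBin(raw_all[(offset + 1):(offset + n * size)], what = what, n = n,
            size = size, endian = endian, signed = signed)
  }
  if (rd(2, 1, 2, signed = FALSE) != 42L) {
    stop("'", path, "' is not a classic TIFF (BigTIFF is unsupported)",
         call. = FALSE)
  }
  ifd_off <- rd(4, 1, 4)
  n <- rd(ifd_off, 1, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n)) {
    e_off <- ifd_off + 2 + (i - 1) * 12
    tag <- rd(e_off, 1, 2, signed = FALSE)
    type <- rd(e_off + 2, 1, 2, signed = FALSE)
    count <- rd(e_off + 4, 1, 4)
    size <- TIFF_TYPE_SIZES[[as.character(type)]]
    total <- size * count
    val_off <- if (total <= 4) e_off + 8 else rd(e_off + 8, 1, 4)
    vals <- switch(as.character(type),
      `2` = { b <- raw_all[(val_off + 1):(val_off + count)]
              rawToChar(b[b != as.raw(0L)]) },
      `3` = rd(val_off, count, 2, signed = FALSE),
      `4` = rd(val_off, count, 4),
      `11` = rd(val_off, count, 4, what = "double"),
      `12` = rd(val_off, count, 8, what = "double"),
      `1` = as.integer(raw_all[(val_off + 1):(val_off + count)]),
      NULL)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag) tags[[as.character(tag)]]

  if (!is.null(need(322)) || !is.null(need(324))) {
    stop("'", path, "': tiled TIFFs are not supported (strip layout required)",
         call. = FALSE)
  }
  spp <- need(277); if (is.null(spp)) spp <- 1L
  if (spp != 1L) {
    stop("'", path, "' is multi-band (", spp,
         " samples per pixel); a single-band raster is required", call. = FALSE)
  }
  comp <- need(259); if (is.null(comp)) comp <- 1L
  if (comp != 1L) {
    stop("'", path, "' is compressed (compression code ", comp,
         "); only uncompressed TIFFs are supported", call. = FALSE)
  }
  nc <- need(256); nr <- need(257)
  bits <- need(258); if (is.null(bits)) bits <- 1L
  fmt <- need(339); if (is.null(fmt)) fmt <- 1L
  if (is.null(nc) || is.null(nr)) stop("'", path, "': missing image dimensions",
                                       call. = FALSE)

  tf <- need(34264)  # ModelTransformation
  if (!is.null(tf) && (tf[2] != 0 || tf[5] != 0)) {
    stop("'", path, "' has a rotated/sheared geotransform; only axis-aligned ",
         "north-up rasters are supported", call. = FALSE)
  }
  scale <- need(33550); tie <- need(33922)
  if (!is.null(tf)) {
    scale <- c(tf[1], -tf[6], 0); tie <- c(0, 0, 0, tf[4], tf[8], 0)
  }
  if (is.null(scale) || is.null(tie)) {
    stop("'", path, "' has no georeferencing (ModelPixelScale/ModelTiepoint ",
         "or ModelTransformation tag required)", call. = FALSE)
  }
  geokeys <- need(34735)
  if (is.null(geokeys)) {
    stop("'", path, "' has no CRS information (GeoKeyDirectory tag missing)",
         call. = FALSE)
  }
  gk <- matrix(geokeys, ncol = 4, byrow = TRUE)
  model_type <- gk[gk[, 1] == 1024L, 4]
  crs <- if (length(model_type) && model_type == 1L) "planar" else "geographic"

  strip_offs <- need(273); strip_counts <- need(279)
  if (is.null(strip_offs)) stop("'", path, "': no strip offsets", call. = FALSE)
  if (is.null(strip_counts)) {
    strip_counts <- rep(nr * nc * bits / 8 / length(strip_offs),
                        length(strip_offs))
  }
  pix_raw <- do.call(c, lapply(seq_along(strip_offs), function(i) {
    raw_all[(strip_offs[i] + 1):(strip_offs[i] + strip_counts[i])]
  }))
  npix <- nr * nc
  pix <- if (fmt == 3L && bits == 32L) {
    readBin(pix_raw, "double", n = npix, size = 4L, endian = endian)
  } else if (fmt == 3L && bits == 64L) {
    readBin(pix_raw, "double", n = npix, size = 8L, endian = endian)
  } else if (fmt %in% c(1L, 2L) && bits %in% c(8L, 16L, 32L)) {
    readBin(pix_raw, "integer", n = npix, size = bits / 8L, endian = endian,
            signed = fmt == 2L || bits > 8L)
  } else {
    stop("'", path, "': unsupported sample layout (format ", fmt, ", ", bits,
         " bits)", call. = FALSE)
  }
  values <- matrix(as.numeric(pix), nr, nc, byrow = TRUE)

  xmin <- tie[4] - tie[1] * scale[1]
  ymax <- tie[5] + tie[2] * scale[2]
  grid <- tt_grid(tt_extent(xmin, xmin + nc * scale[1],
                            ymax - nr * scale[2], ymax, crs = crs),
                  scale[1], scale[2])
  nodata <- if (!is.null(need(42113))) suppressWarnings(as.numeric(need(42113)))
            else NULL
  list(values = values, grid = grid, nodata = nodata,
       description = need(270))
}
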