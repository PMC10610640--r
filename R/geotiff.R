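# Minimal GeoTIFF codec (classic TIFF, uncompressed, stripped).
# Supports float32/float64 and uint8/16/32 samples, single or multiple
# interleaved bands, ModelPixelScale + ModelTiepoint georeferencing, a CRS
# citation string, and the GDAL nodata tag. Deliberately rejects compressed
# or tiled files: the pipeline writes its own inputs.

TIFF_TYPE_SIZES <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8,
                     `6` = 1, `7` = 1, `8` = 2, `9` = 4, `10` = 8,
                     `11` = 4, `12` = 8)

#' Read a single- or multi-band GeoTIFF
#'
#' Reads an uncompressed, strip-organised GeoTIFF written by
#' [write_raster()] or compatible tooling. Cells equal to the file's nodata
#' tag become `NA`. Files without an affine georeference or CRS citation are
#' rejected -- the pipeline refuses to guess geotags.
#'
#' @param path Path to a GeoTIFF file.
#' @param band 1-based band to extract (bands are pixel-interleaved).
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, band = 1L) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readBin(con, "raw", 2)
  endian <- if (identical(order_bytes, charToRaw("II"))) "little"
            else if (identical(order_bytes, charToRaw("MM"))) "big"
            else stop("not a TIFF file: ", path)
  magic <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  if (magic != 42) stop("not a classic TIFF file: ", path)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)

  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                       endian = endian)
  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    value_raw <- readBin(con, "raw", 4)
    entries[[i]] <- list(tag = tag, type = type, count = count,
                         value_raw = value_raw)
  }
  read_entry <- function(e) {
    size <- TIFF_TYPE_SIZES[[as.character(e$type)]]
    nbytes <- size * e$count
    raw <- if (nbytes <= 4) e$value_raw[seq_len(nbytes)] else {
      off <- readBin(e$value_raw, "integer", 1, size = 4, endian = endian)
      seek(con, off)
      readBin(con, "raw", nbytes)
    }
    switch(as.character(e$type),
      `2` = rawToChar(raw[raw != as.raw(0)]),
      `3` = readBin(raw, "integer", e$count, size = 2, signed = FALSE,
                    endian = endian),
      `4` = readBin(raw, "integer", e$count, size = 4, endian = endian),
      `11` = readBin(raw, "double", e$count, size = 4, endian = endian),
      `12` = readBin(raw, "double", e$count, size = 8, endian = endian),
      readBin(raw, "integer", min(e$count, length(raw)), size = 1,
              signed = FALSE, endian = endian))
  }
  tags <- vapply(entries, `[[`, 0L, "tag")
  get_tag <- function(tag, default = NULL) {
    i <- match(tag, tags)
    if (is.na(i)) default else read_entry(entries[[i]])
  }

  if (!is.null(get_tag(322L)) || !is.null(get_tag(324L)))
    stop("tiled TIFFs are not supported")
  compression <- get_tag(259L, 1L)
  if (compression != 1L)
    stop("compressed TIFFs are not supported (compression tag ", compression, ")")
  width <- get_tag(256L); height <- get_tag(257L)
  if (is.null(width) || is.null(height)) stop("TIFF missing image dimensions")
  spp <- get_tag(277L, 1L)
  if (band < 1 || band > spp)
    stop(sprintf("band %d requested but file has %d band(s)", band, spp))
  bits <- get_tag(258L, 8L)[1]
  fmt <- get_tag(339L, 1L)[1]  # 1 = unsigned int, 2 = signed, 3 = IEEE float
  planar <- get_tag(284L, 1L)
  if (planar != 1L) stop("only pixel-interleaved (chunky) TIFFs are supported")

  strip_offsets <- get_tag(273L)
  strip_counts <- get_tag(279L)
  if (is.null(strip_offsets) || is.null(strip_counts))
    stop("TIFF missing strip layout")
  raw <- raw(0)
  for (s in seq_along(strip_offsets)) {
    seek(con, strip_offsets[s])
    raw <- c(raw, readBin(con, "raw", strip_counts[s]))
  }
  n_samples <- width * height * spp
  values <- if (fmt == 3L) {
    readBin(raw, "double", n_samples, size = bits / 8, endian = endian)
  } else {
    readBin(raw, "integer", n_samples, size = bits / 8,
            signed = (fmt == 2L || bits == 32), endian = endian)
  }
  band_vals <- values[seq(band, n_samples, by = spp)]
  mat <- matrix(as.numeric(band_vals), nrow = height, ncol = width,
                byrow = TRUE)

  scale <- get_tag(33550L)
  tiepoint <- get_tag(33922L)
  if (is.null(scale) || is.null(tiepoint))
    stop("GeoTIFF missing georeferencing (ModelPixelScale/ModelTiepoint): ",
         path)
  ascii_params <- get_tag(34737L)
  geokeys <- get_tag(34735L)
  crs <- NULL
  if (!is.null(geokeys) && length(geokeys) >= 8) {
    keys <- matrix(geokeys[-(1:4)], ncol = 4, byrow = TRUE)
    cit <- keys[keys[, 1] == 1026, , drop = FALSE]
    if (nrow(cit) == 1 && !is.null(ascii_params)) {
      crs <- substr(ascii_params, cit[1, 4] + 1, cit[1, 4] + cit[1, 3])
      crs <- sub("\\|+$", "", crs)
    }
    if (is.null(crs) || !nzchar(crs)) {
      epsg <- keys[keys[, 1] == 3072, , drop = FALSE]
      if (nrow(epsg) == 1) crs <- paste0("EPSG:", epsg[1, 4])
    }
  }
  if (is.null(crs) || !nzchar(crs))
    stop("GeoTIFF missing CRS metadata (no citation or EPSG geokey): ", path)

  nodata_str <- get_tag(42113L)
  nodata <- if (is.null(nodata_str)) -9999 else as.numeric(nodata_str)
  if (is.finite(nodata)) mat[mat == nodata] <- NA_real_
  # tiepoint maps raster point (j, i) -> model (x, y); we require the
  # top-left corner convention
  xmin <- tiepoint[4] - tiepoint[1] * scale[1]
  ymax <- tiepoint[5] + tiepoint[2] * scale[2]
  raster_grid(mat, xmin = xmin, ymax = ymax, dx = scale[1], dy = scale[2],
              crs = crs, nodata = nodata)
}

#' Write a raster grid as GeoTIFF
#'
#' Writes an uncompressed little-endian GeoTIFF with affine georeferencing
#' (ModelPixelScale + ModelTiepoint), the CRS label as a GeoTIFF citation,
#' and the nodata sentinel in the GDAL nodata tag. `NA` cells are stored as
#' the sentinel. Values are not clipped or transformed: a CWSI grid with
#' values outside \[0, 1\] round-trips unchanged.
#'
#' @param grid A [raster_grid()], or a list of them with identical geometry
#'   to write a multi-band (pixel-interleaved) file.
#' @param path Output path.
#' @param dtype `"float32"` (default, matches common thermal products),
#'   `"float64"` for lossless doubles, or `"uint8"` for binary masks.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, dtype = c("float32", "float64", "uint8")) {
  dtype <- match.arg(dtype)
  bands <- if (is_raster_grid(grid)) list(grid) else grid
  if (!length(bands) || !all(vapply(bands, is_raster_grid, TRUE)))
    stop("grid must be a raster_grid or a list of raster_grid bands")
  grid <- bands[[1]]
  for (b in bands[-1]) check_same_geometry(grid, b, "bands")
  nbands <- length(bands)
  dirn <- dirname(path)
  if (!dir.exists(dirn)) stop("output directory does not exist: ", dirn)
  height <- nrow(grid$values); width <- ncol(grid$values)
  # pixel-interleaved row-major sample order
  vals <- do.call(rbind, lapply(bands, function(b) as.vector(t(b$values))))
  vals <- as.vector(vals)
  vals[!is.finite(vals)] <- grid$nodata
  if (dtype == "uint8" && (min(vals) < 0 || max(vals) > 255))
    stop("uint8 output requires values in 0..255 (set a nodata code in range)")

  bits <- switch(dtype, float32 = 32L, float64 = 64L, uint8 = 8L)
  fmt <- if (dtype == "uint8") 1L else 3L
  pixel_bytes <- as.integer(bits / 8)
  data_bytes <- width * height * nbands * pixel_bytes

  crs_ascii <- paste0(grid$crs, "|")
  crs_raw <- c(charToRaw(crs_ascii), as.raw(0))
  nodata_ascii <- format(grid$nodata, scientific = FALSE, trim = TRUE)
  nodata_raw <- c(charToRaw(nodata_ascii), as.raw(0))
  # TIFF stores values of <= 4 bytes inline in the entry's value field
  crs_inline <- length(crs_raw) <= 4
  nodata_inline <- length(nodata_raw) <= 4
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 1,      # model type: projected
                          1025, 0, 1, 1,      # raster type: pixel-is-area
                          1026, 34737, length(crs_raw), 0))
  doubles_scale <- c(grid$dx, grid$dy, 0)
  doubles_tie <- c(0, 0, 0, grid$xmin, grid$ymax, 0)

  # layout: 8-byte header | pixel data | aux arrays | IFD
  off_data <- 8L
  off_scale <- off_data + data_bytes
  if (off_scale %% 2 == 1) off_scale <- off_scale + 1L
  off_tie <- off_scale + 24L
  off_geokeys <- off_tie + 48L
  off_ascii <- off_geokeys + length(geokeys) * 2L
  off_nodata <- off_ascii + (if (crs_inline) 0L else length(crs_raw))
  off_bits <- off_nodata + (if (nodata_inline) 0L else length(nodata_raw))
  if (off_bits %% 2 == 1) off_bits <- off_bits + 1L
  extra_arrays <- if (nbands > 2) 2L * nbands * 2L else 0L
  off_fmt <- off_bits + (if (nbands > 2) nbands * 2L else 0L)
  off_ifd <- off_bits + extra_arrays
  if (off_ifd %% 2 == 1) off_ifd <- off_ifd + 1L

  ushort_raw <- function(v) {
    v <- as.integer(v)
    v[v > 32767L] <- v[v > 32767L] - 65536L  # reinterpret as signed for writeBin
    writeBin(v, raw(), size = 2, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    # value: raw vector (inline), integers fitting into 4 bytes, or an offset
    v_raw <- raw(4)
    size <- TIFF_TYPE_SIZES[[as.character(type)]]
    enc <- if (is.raw(value)) {
      stopifnot(length(value) <= 4)
      value
    } else if (size * count <= 4 && size == 2) {
      ushort_raw(value)
    } else {
      stopifnot(size * count <= 4 || length(value) == 1)
      writeBin(as.integer(value), raw(),
               size = if (size * count <= 4) size else 4, endian = "little")
    }
    v_raw[seq_along(enc)] <- enc
    c(ushort_raw(c(tag, type)),
      writeBin(as.integer(count), raw(), size = 4, endian = "little"),
      v_raw)
  }
  entries <- list(
    entry(256L, 4L, 1L, width),
    entry(257L, 4L, 1L, height),
    entry(258L, 3L, nbands, if (nbands <= 2) rep(bits, nbands) else off_bits),
    entry(259L, 3L, 1L, 1L),
    entry(262L, 3L, 1L, 1L),
    entry(273L, 4L, 1L, off_data),
    entry(277L, 3L, 1L, nbands),
    entry(278L, 4L, 1L, height),
    entry(279L, 4L, 1L, data_bytes),
    entry(284L, 3L, 1L, 1L),
    entry(339L, 3L, nbands, if (nbands <= 2) rep(fmt, nbands) else off_fmt),
    entry(33550L, 12L, 3L, off_scale),
    entry(33922L, 12L, 6L, off_tie),
    entry(34735L, 3L, length(geokeys), off_geokeys),
    entry(34737L, 2L, length(crs_raw), if (crs_inline) crs_raw else off_ascii),
    entry(42113L, 2L, length(nodata_raw),
          if (nodata_inline) nodata_raw else off_nodata))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(off_ifd, con, size = 4, endian = "little")
  if (dtype == "uint8") {
    writeBin(as.integer(as.vector(vals)), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(as.vector(vals)), con, size = pixel_bytes,
             endian = "little")
  }
  pad_to <- function(target) {
    here <- seek(con, NA)
    if (here < target) writeBin(raw(target - here), con)
  }
  pad_to(off_scale)
  writeBin(doubles_scale, con, size = 8, endian = "little")
  writeBin(doubles_tie, con, size = 8, endian = "little")
  writeBin(ushort_raw(geokeys), con)
  if (!crs_inline) writeBin(crs_raw, con)
  if (!nodata_inline) writeBin(nodata_raw, con)
  if (nbands > 2) {
    pad_to(off_bits)
    writeBin(ushort_raw(rep(bits, nbands)), con)
    writeBin(ushort_raw(rep(fmt, nbands)), con)
  }
  pad_to(off_ifd)
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) writeBin(e, con)
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}
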