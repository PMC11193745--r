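# Minimal GeoTIFF codec for single-band integer rasters.
#
# Scope: baseline TIFF, uncompressed, strip-organized, one sample per pixel,
# 8/16/32-bit integer samples, either byte order on read, little-endian on
# write. Georeferencing via ModelPixelScaleTag + ModelTiepointTag (the
# north-up geotransform); rasters carrying a ModelTransformationTag
# (rotation/shear) are rejected. The nodata value is carried in the
# GDAL_NODATA ASCII tag; the CRS tag string is carried in ImageDescription as
# "crs=<tag>". This covers exactly what the analysis grid model needs and
# what common GIS tooling writes for such masks; it is not a general TIFF
# library.

TIFF_TAG <- list(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, description = 270L, strip_offsets = 273L,
  orientation = 274L, samples_per_pixel = 277L, rows_per_strip = 278L,
  strip_bytes = 279L, planar = 284L, sample_format = 339L,
  model_pixel_scale = 33550L, model_tiepoint = 33922L,
  model_transformation = 34264L, gdal_nodata = 42113L)

# ---- writing ---------------------------------------------------------------

w_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
w_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")
w_dbl <- function(con, x) writeBin(as.numeric(x), con, size = 8, endian = "little")

#' Write a label grid as a single-band uint8 GeoTIFF
#'
#' Writes an uncompressed, little-endian, north-up GeoTIFF with
#' georeferencing (`ModelPixelScale`, `ModelTiepoint`), the nodata code in
#' the `GDAL_NODATA` tag and the CRS tag string in `ImageDescription`.
#' Files round-trip exactly through [read_label_grid()].
#'
#' @param grid A [label_grid()] (values must fit in uint8).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_grid <- function(grid, path) {
  stopifnot(inherits(grid, "label_grid"))
  if (any(grid$labels < 0L | grid$labels > 255L))
    stop("labels exceed uint8 range")
  write_geotiff_uint8(grid$labels, grid$spec, path,
                      nodata = grid$nodata_code)
}

# core writer; `transform` (16 doubles) is only used to fabricate rotated
# fixtures for the reader's rejection path
write_geotiff_uint8 <- function(values, spec, path, nodata = NULL,
                                transform = NULL) {
  stopifnot(is.matrix(values), inherits(spec, "grid_spec"))
  nr <- nrow(values); nc <- ncol(values)
  if (nr != spec$n_rows || nc != spec$n_cols)
    stop("value dimensions do not match spec")

  desc <- charToRaw(paste0("crs=", spec$crs_tag)); desc <- c(desc, as.raw(0))
  nd_raw <- if (!is.null(nodata)) c(charToRaw(as.character(nodata)), as.raw(0))

  entries <- list(
    list(tag = TIFF_TAG$width, type = 4L, values = nc),
    list(tag = TIFF_TAG$length, type = 4L, values = nr),
    list(tag = TIFF_TAG$bits, type = 3L, values = 8L),
    list(tag = TIFF_TAG$compression, type = 3L, values = 1L),
    list(tag = TIFF_TAG$photometric, type = 3L, values = 1L),
    list(tag = TIFF_TAG$description, type = 2L, values = desc),
    list(tag = TIFF_TAG$strip_offsets, type = 4L, values = NA), # patched below
    list(tag = TIFF_TAG$orientation, type = 3L, values = 1L),
    list(tag = TIFF_TAG$samples_per_pixel, type = 3L, values = 1L),
    list(tag = TIFF_TAG$rows_per_strip, type = 4L, values = nr),
    list(tag = TIFF_TAG$strip_bytes, type = 4L, values = nr * nc),
    list(tag = TIFF_TAG$planar, type = 3L, values = 1L),
    list(tag = TIFF_TAG$sample_format, type = 3L, values = 1L))
  if (is.null(transform)) {
    entries <- c(entries, list(
      list(tag = TIFF_TAG$model_pixel_scale, type = 12L,
           values = c(spec$pixel_size, spec$pixel_size, 0)),
      list(tag = TIFF_TAG$model_tiepoint, type = 12L,
           values = c(0, 0, 0, spec$origin_x, spec$origin_y, 0))))
  } else {
    stopifnot(length(transform) == 16L)
    entries <- c(entries, list(
      list(tag = TIFF_TAG$model_transformation, type = 12L,
           values = transform)))
  }
  if (!is.null(nd_raw))
    entries <- c(entries, list(
      list(tag = TIFF_TAG$gdal_nodata, type = 2L, values = nd_raw)))
  entries <- entries[order(vapply(entries, function(e) e$tag, 0L))]

  type_size <- c(`2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  entry_bytes <- function(e) {
    n <- if (e$type == 2L) length(e$values) else length(e$values)
    n * type_size[[as.character(e$type)]]
  }
  n_ent <- length(entries)
  ifd_off <- 8L
  ifd_size <- 2L + n_ent * 12L + 4L
  data_off <- ifd_off + ifd_size           # out-of-line tag values start here
  overflow <- vapply(entries, function(e) entry_bytes(e) > 4L, TRUE)
  off <- data_off
  value_offsets <- integer(n_ent)
  for (i in seq_len(n_ent)) {
    if (overflow[i]) { value_offsets[i] <- off; off <- off + entry_bytes(entries[[i]]) }
    if (off %% 2L == 1L) off <- off + 1L   # word alignment
  }
  strip_off <- off
  entries[[which(vapply(entries, function(e) e$tag == TIFF_TAG$strip_offsets, TRUE))]]$values <- strip_off

  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con); w_u16(con, 42L); w_u32(con, ifd_off)
  w_u16(con, n_ent)
  for (i in seq_len(n_ent)) {
    e <- entries[[i]]
    n <- length(e$values)
    w_u16(con, e$tag); w_u16(con, e$type); w_u32(con, n)
    if (!overflow[i]) {
      if (e$type == 2L) {
        pad <- c(e$values, rep(as.raw(0), 4L - n)); writeBin(pad, con)
      } else if (e$type == 3L) {
        w_u16(con, e$values); if (n == 1L) w_u16(con, 0L)
      } else w_u32(con, e$values)
    } else w_u32(con, value_offsets[i])
  }
  w_u32(con, 0L)                           # no next IFD
  pos <- ifd_off + ifd_size
  for (i in seq_len(n_ent)) {
    e <- entries[[i]]
    if (overflow[i]) {
      if (e$type == 2L) writeBin(e$values, con)
      else if (e$type == 3L) w_u16(con, e$values)
      else if (e$type == 4L) w_u32(con, e$values)
      else w_dbl(con, e$values)
      pos <- pos + entry_bytes(e)
    }
    if (pos %% 2L == 1L) { writeBin(as.raw(0), con); pos <- pos + 1L }
  }
  writeBin(as.raw(as.vector(t(values))), con) # TIFF rows are sequential
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

#' Read a single-band integer GeoTIFF
#'
#' Low-level reader returning the raw class-code matrix plus the grid spec
#' derived from the geotransform; values are returned unmodified (use
#' [binarize()] to map product codes to cropland labels, or
#' [read_label_grid()] for already-binary rasters). Only north-up rasters are
#' accepted: a `ModelTransformationTag` (rotation/shear) is rejected.
#'
#' @param path Path to a GeoTIFF file.
#' @param band Band index; only single-band rasters are supported, so this
#'   must be 1.
#' @return A list with `values` (integer matrix), `spec` ([grid_spec()]) and
#'   `nodata` (integer or `NA` if the file declares none).
#' @export
read_raster <- function(path, band = 1L) {
  if (!file.exists(path)) stop("missing file: ", path)
  if (band != 1L) stop("only single-band rasters are supported")
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file: ", path)
  rd <- function(at, size, n = 1L, signed = TRUE, what = "integer")
    readBin(raw[(at + 1L):(at + size * n)], what, n = n, size = size,
            endian = endian, signed = signed)
  if (rd(2L, 2L, signed = FALSE) != 42L) stop("not a TIFF file: ", path)
  ifd <- rd(4L, 4L)
  n_ent <- rd(ifd, 2L, signed = FALSE)
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  tags <- list()
  for (i in seq_len(n_ent)) {
    at <- ifd + 2L + (i - 1L) * 12L
    tag <- rd(at, 2L, signed = FALSE)
    type <- rd(at + 2L, 2L, signed = FALSE)
    cnt <- rd(at + 4L, 4L)
    if (!as.character(type) %in% names(type_size)) next
    sz <- type_size[[as.character(type)]]
    src <- if (sz * cnt <= 4L) at + 8L else rd(at + 8L, 4L)
    vals <- switch(as.character(type),
      `1` = rd(src, 1L, cnt, signed = FALSE),
      `2` = rawToChar(raw[(src + 1L):(src + cnt)][raw[(src + 1L):(src + cnt)] != as.raw(0)]),
      `3` = rd(src, 2L, cnt, signed = FALSE),
      `4` = rd(src, 4L, cnt),
      `12` = rd(src, 8L, cnt, what = "numeric"))
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  if (!is.null(g(TIFF_TAG$model_transformation)))
    stop("non-north-up raster: ModelTransformation (rotation/shear) is not supported")
  if (!identical(g(TIFF_TAG$orientation, 1L), 1L) &&
      g(TIFF_TAG$orientation, 1L) != 1)
    stop("non-north-up raster: unsupported orientation")
  if (g(TIFF_TAG$compression, 1L) != 1) stop("compressed TIFF not supported")
  if (g(TIFF_TAG$samples_per_pixel, 1L) != 1)
    stop("only single-band rasters are supported")
  fmt <- g(TIFF_TAG$sample_format, 1L)
  if (!fmt %in% c(1, 2))
    stop("non-integer samples: only unsigned/signed integer rasters are supported")
  bits <- g(TIFF_TAG$bits, 1L)
  if (!bits %in% c(8, 16, 32)) stop("unsupported bit depth: ", bits)
  nc <- g(TIFF_TAG$width); nr <- g(TIFF_TAG$length)
  if (is.null(nc) || is.null(nr)) stop("malformed TIFF: missing dimensions")
  scale <- g(TIFF_TAG$model_pixel_scale)
  tie <- g(TIFF_TAG$model_tiepoint)
  if (is.null(scale) || is.null(tie))
    stop("no georeferencing: ModelPixelScale/ModelTiepoint tags required")
  if (abs(scale[1] - scale[2]) > 1e-9 * scale[1])
    stop("non-square pixels are not supported")
  origin_x <- tie[4] - tie[1] * scale[1]
  origin_y <- tie[5] + tie[2] * scale[2]
  desc <- g(TIFF_TAG$description, "")
  crs_tag <- if (startsWith(desc, "crs=")) sub("^crs=", "", desc) else "unspecified"
  nd <- g(TIFF_TAG$gdal_nodata)
  nodata <- if (is.null(nd)) NA_integer_ else as.integer(as.numeric(nd))

  offsets <- g(TIFF_TAG$strip_offsets)
  counts <- g(TIFF_TAG$strip_bytes)
  rps <- g(TIFF_TAG$rows_per_strip, nr)
  bpp <- bits / 8
  vals <- matrix(0L, nr, nc)
  row0 <- 0L
  for (s in seq_along(offsets)) {
    nrow_s <- min(rps, nr - row0)
    v <- rd(offsets[s], bpp, nrow_s * nc, signed = (fmt == 2 || bits == 32),
            what = "integer")
    vals[row0 + seq_len(nrow_s), ] <- matrix(v, nrow_s, nc, byrow = TRUE)
    row0 <- row0 + nrow_s
  }
  list(values = vals,
       spec = grid_spec(origin_x, origin_y, scale[1], nr, nc, crs_tag),
       nodata = nodata)
}

#' Read an already-binary cropland GeoTIFF as a label grid
#'
#' Convenience wrapper around [read_raster()] for rasters whose values are
#' already in {0, 1, nodata}.
#'
#' @inheritParams read_raster
#' @param nodata_code Nodata code to assume when the file declares none.
#' @return A [label_grid()].
#' @export
read_label_grid <- function(path, band = 1L, nodata_code = 255L) {
  r <- read_raster(path, band)
  nd <- if (is.na(r$nodata)) as.integer(nodata_code) else r$nodata
  label_grid(r$spec, r$values, nodata_code = nd)
}
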