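#' Grid specification for a north-up, square-pixel raster
#'
#' A `grid_spec` pins a raster to map coordinates: the outer top-left corner
#' (`origin_x`, `origin_y`), a positive square pixel size, the grid dimensions
#' and an opaque CRS tag. The CRS is assumed equal-area so that
#' pixel count times pixel area is a valid area estimate; no reprojection is
#' performed by this package — co-registration is a precondition, checked via
#' the tag and the geotransform.
#'
#' Pixels are half-open `[edge, edge + size)` cells; row 1 is the
#' northernmost row. A point (x, y) falls in
#' `col = floor((x - origin_x)/pixel_size) + 1`,
#' `row = floor((origin_y - y)/pixel_size) + 1`.
#'
#' @param origin_x,origin_y Easting/northing of the outer top-left corner, in
#'   map units (metres for a projected equal-area CRS).
#' @param pixel_size Pixel edge length in map units; must be positive.
#' @param n_rows,n_cols Grid dimensions, at least 1.
#' @param crs_tag Opaque CRS identifier string (e.g. an equal-area PCS label).
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(0, 3000, 30, 100, 100, "albers-equal-area")
#' @export
grid_spec <- function(origin_x, origin_y, pixel_size, n_rows, n_cols,
                      crs_tag = "unspecified") {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y),
            is.numeric(pixel_size), length(pixel_size) == 1L)
  if (pixel_size <= 0) stop("pixel_size must be positive")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size = as.numeric(pixel_size),
         n_rows = n_rows, n_cols = n_cols, crs_tag = as.character(crs_tag)),
    class = "grid_spec")
}

#' Test whether two grid specs describe the same analysis grid
#'
#' Two specs are aligned iff every field matches (origin, pixel size,
#' dimensions, CRS tag). All multi-grid operations require alignment.
#'
#' @param a,b `grid_spec` objects.
#' @param tol Numeric tolerance on origin and pixel size, in map units.
#' @return `TRUE` or `FALSE`.
#' @export
specs_aligned <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$pixel_size - b$pixel_size) <= tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    identical(a$crs_tag, b$crs_tag)
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!specs_aligned(a, b)) stop("misaligned ", what,
                                 ": operations require identical grid specs")
  invisible(TRUE)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d @ %g map units, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_tag))
  invisible(x)
}

# row/col indices (1-based) of points; points outside the grid get NA
point_to_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$pixel_size) + 1
  row <- floor((spec$origin_y - y) / spec$pixel_size) + 1
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

# map coordinates of pixel centers
cell_center <- function(spec, row, col) {
  list(x = spec$origin_x + (col - 0.5) * spec$pixel_size,
       y = spec$origin_y - (row - 0.5) * spec$pixel_size)
}

#' Binary label grid
#'
#' The universal map representation: a georeferenced matrix over
#' {0 = non-cropland, 1 = cropland, `nodata_code`}. Values are stored exactly
#' as coded (the nodata code is a reserved integer, 255 by default, matching
#' the uint8 GeoTIFF convention).
#'
#' @param spec A [grid_spec()].
#' @param labels Integer matrix `n_rows x n_cols` over {0, 1, nodata_code}.
#' @param nodata_code Reserved integer outside {0, 1}; default 255.
#' @return An object of class `label_grid`.
#' @export
label_grid <- function(spec, labels, nodata_code = 255L) {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(labels))
  if (!all(dim(labels) == c(spec$n_rows, spec$n_cols)))
    stop("labels dimensions do not match spec")
  nodata_code <- as.integer(nodata_code)
  if (nodata_code %in% c(0L, 1L)) stop("nodata_code must be outside {0, 1}")
  storage.mode(labels) <- "integer"
  ok <- labels %in% c(0L, 1L, nodata_code)
  if (!all(ok)) stop("labels must be 0, 1 or the nodata code; found ",
                     paste(utils::head(unique(labels[!ok]), 5), collapse = ", "))
  structure(list(spec = spec, labels = labels, nodata_code = nodata_code),
            class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  n_nd <- sum(x$labels == x$nodata_code)
  n1 <- sum(x$labels == 1L)
  cat(sprintf("label_grid: %d x %d, %d cropland, %d nodata\n",
              x$spec$n_rows, x$spec$n_cols, n1, n_nd))
  print(x$spec)
  invisible(x)
}

#' Class-code mapping for a land-cover product
#'
#' Declares which raw class codes of a product mean cropland and which are
#' nodata; every other code is non-cropland by contract.
#'
#' @param product_name Product identifier string.
#' @param cropland_codes Non-empty integer vector of cropland class codes.
#' @param nodata_codes Integer vector of nodata codes (may be empty); must be
#'   disjoint from `cropland_codes`.
#' @return An object of class `class_map`.
#' @examples
#' class_map("sino-lc1", cropland_codes = 5)
#' @export
class_map <- function(product_name, cropland_codes, nodata_codes = integer()) {
  cropland_codes <- as.integer(cropland_codes)
  nodata_codes <- as.integer(nodata_codes)
  if (length(cropland_codes) == 0L) stop("cropland_codes must be non-empty")
  if (length(intersect(cropland_codes, nodata_codes)) > 0L)
    stop("cropland_codes and nodata_codes must be disjoint")
  structure(list(product_name = as.character(product_name),
                 cropland_codes = cropland_codes,
                 nodata_codes = nodata_codes),
            class = "class_map")
}

#' Binarize a raw class-code grid into a cropland label grid
#'
#' Cells whose code is in `cropland_codes` become 1, cells in `nodata_codes`
#' become nodata, everything else becomes 0. Unlisted codes are non-cropland
#' by contract, so binarization never errors on unexpected codes.
#'
#' @param raw Integer matrix of product class codes.
#' @param cmap A [class_map()].
#' @param spec The [grid_spec()] of `raw`.
#' @param nodata_code Nodata code for the output grid.
#' @return A [label_grid()].
#' @export
binarize <- function(raw, cmap, spec, nodata_code = 255L) {
  stopifnot(is.matrix(raw), inherits(cmap, "class_map"))
  out <- matrix(0L, nrow(raw), ncol(raw))
  out[raw %in% cmap$cropland_codes] <- 1L
  out[raw %in% cmap$nodata_codes] <- as.integer(nodata_code)
  label_grid(spec, out, nodata_code = nodata_code)
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Each target cell takes the label of the source cell containing the target
#' cell's center; target cells whose center falls outside the source extent
#' become nodata. This is the standard categorical-raster harmonization step
#' (e.g. bringing heterogeneous products onto a common 30 m grid).
#'
#' @param grid A [label_grid()].
#' @param target Target [grid_spec()]; must share `crs_tag` with the source.
#' @return A [label_grid()] on `target`.
#' @export
resample_nearest <- function(grid, target) {
  stopifnot(inherits(grid, "label_grid"), inherits(target, "grid_spec"))
  s <- grid$spec
  if (!identical(s$crs_tag, target$crs_tag))
    stop("crs mismatch: cannot resample across coordinate systems")
  cx <- target$origin_x + (seq_len(target$n_cols) - 0.5) * target$pixel_size
  cy <- target$origin_y - (seq_len(target$n_rows) - 0.5) * target$pixel_size
  sc <- floor((cx - s$origin_x) / s$pixel_size) + 1
  sr <- floor((s$origin_y - cy) / s$pixel_size) + 1
  out <- matrix(grid$nodata_code, target$n_rows, target$n_cols)
  ok_c <- which(sc >= 1 & sc <= s$n_cols)
  ok_r <- which(sr >= 1 & sr <= s$n_rows)
  if (length(ok_r) && length(ok_c))
    out[ok_r, ok_c] <- grid$labels[sr[ok_r], sc[ok_c], drop = FALSE]
  label_grid(target, out, nodata_code = grid$nodata_code)
}

#' Clip a grid by a binary mask
#'
#' Cells where the mask is 0 or nodata become nodata; cells where the mask is
#' 1 pass through unchanged. Used to restrict products to the study-area
#' boundary.
#'
#' @param grid,mask Aligned [label_grid()]s.
#' @return A [label_grid()].
#' @export
clip_mask <- function(grid, mask) {
  stopifnot(inherits(grid, "label_grid"), inherits(mask, "label_grid"))
  stop_if_misaligned(grid$spec, mask$spec)
  out <- grid$labels
  out[mask$labels != 1L] <- grid$nodata_code
  label_grid(grid$spec, out, nodata_code = grid$nodata_code)
}

#' Per-pixel temporal majority composite of a label-grid stack
#'
#' For each cell, the label (0 or 1) with the most non-nodata occurrences in
#' the stack; cells that are nodata in every layer stay nodata. Used to
#' collapse sub-annual classifications into an annual composite map.
#'
#' @param grids Non-empty list of aligned [label_grid()]s.
#' @param tie Label assigned when 0 and 1 occur equally often: `"cropland"`
#'   (default, favours detection) or `"noncropland"`.
#' @return A [label_grid()].
#' @export
temporal_majority <- function(grids, tie = c("cropland", "noncropland")) {
  tie <- match.arg(tie)
  if (!length(grids)) stop("empty list of grids")
  stopifnot(all(vapply(grids, inherits, TRUE, "label_grid")))
  for (g in grids[-1]) stop_if_misaligned(grids[[1]]$spec, g$spec)
  n1 <- Reduce(`+`, lapply(grids, function(g) g$labels == 1L))
  n0 <- Reduce(`+`, lapply(grids, function(g) g$labels == 0L))
  out <- matrix(grids[[1]]$nodata_code, nrow(n1), ncol(n1))
  out[n1 > n0] <- 1L
  out[n0 > n1] <- 0L
  eq <- n1 == n0 & n1 + n0 > 0
  out[eq] <- if (tie == "cropland") 1L else 0L
  label_grid(grids[[1]]$spec, out, nodata_code = grids[[1]]$nodata_code)
}

#' Mapped cropland area of a label grid
#'
#' Count of cropland cells times the pixel area, reported in units of
#' 10^4 ha (the census convention). Assumes an equal-area CRS with map units
#' in metres, so one 30 m pixel is 0.09 ha. Nodata cells are excluded.
#'
#' @param grid A [label_grid()].
#' @return Area in 10^4 ha.
#' @export
mapped_area <- function(grid) {
  stopifnot(inherits(grid, "label_grid"))
  n1 <- sum(grid$labels == 1L)
  # m^2 -> ha is /1e4, ha -> 10^4 ha is /1e4 again
  n1 * grid$spec$pixel_size^2 / 1e8
}
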