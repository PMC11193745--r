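#' Zone raster
#'
#' An integer raster of administrative-unit ids aligned with the analysis
#' grid (rasterized upstream from polygons); `NA` marks cells outside every
#' zone. An optional `group` attribute maps zone ids to a coarser level
#' (e.g. counties to provinces) for multi-level comparison.
#'
#' @param spec A [grid_spec()].
#' @param zones Integer matrix of zone ids (`NA` allowed).
#' @param group Optional data frame `zone`, `group` mapping ids to a coarser
#'   grouping.
#' @return An object of class `zone_grid`.
#' @export
zone_grid <- function(spec, zones, group = NULL) {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(zones))
  if (!all(dim(zones) == c(spec$n_rows, spec$n_cols)))
    stop("zone dimensions do not match spec")
  storage.mode(zones) <- "integer"
  structure(list(spec = spec, zones = zones, group = group),
            class = "zone_grid")
}

#' Mapped cropland area per zone
#'
#' Cropland cell count per zone id times the pixel area, in 10^4 ha;
#' nodata map cells are excluded. Zones with no cropland report 0.
#'
#' @param grid A [label_grid()].
#' @param zones A [zone_grid()] aligned with `grid`.
#' @return Data frame `zone`, `area_1e4ha`, one row per zone id present in
#'   the zone raster.
#' @export
zonal_area <- function(grid, zones) {
  stopifnot(inherits(grid, "label_grid"), inherits(zones, "zone_grid"))
  stop_if_misaligned(grid$spec, zones$spec)
  zids <- sort(unique(as.vector(zones$zones)))
  zids <- zids[!is.na(zids)]
  is1 <- grid$labels == 1L
  cnt <- vapply(zids, function(z)
    sum(is1 & !is.na(zones$zones) & zones$zones == z), 0)
  data.frame(zone = zids,
             area_1e4ha = cnt * grid$spec$pixel_size^2 / 1e8)
}

#' Census-agreement R-squared
#'
#' The skill score `1 - sum((x - y)^2) / sum((y - mean(y))^2)` measuring
#' agreement of mapped areas `x` with census areas `y` against the 1:1
#' line. This is *not* an OLS fit or a squared Pearson correlation: it can
#' be negative (worse than predicting the census mean) and equals 1 only
#' when `x = y` elementwise. For the ambiguous "R^2" reading see
#' [compare_table()], which reports the squared Pearson correlation
#' alongside.
#'
#' @param x Mapped areas.
#' @param y Census areas (must not be constant).
#' @return A scalar `<= 1`.
#' @export
r2_agreement <- function(x, y) {
  stopifnot(length(x) == length(y), length(y) >= 2)
  ss <- sum((y - mean(y))^2)
  if (ss == 0) stop("census areas are constant: R^2 denominator is zero")
  1 - sum((x - y)^2) / ss
}

#' Root-mean-square error of mapped vs census areas
#'
#' `sqrt(sum((x - y)^2) / n)`, in the units of the inputs (10^4 ha for
#' census comparison).
#'
#' @param x Mapped areas.
#' @param y Census areas.
#' @return Non-negative scalar.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  sqrt(sum((x - y)^2) / length(x))
}

#' Compare mapped areas of several maps against census, per zone
#'
#' Joins each map's zonal areas with the census table by zone id, applies
#' configured exclusions (the census analogue of dropping units whose
#' administrative level does not match), and reports the agreement
#' R-squared, squared Pearson correlation, RMSE and total bias per map.
#' Unmatched zone ids are reported via a warning and an attribute, never
#' silently dropped.
#'
#' @param maps Named list of [label_grid()]s.
#' @param zones A [zone_grid()].
#' @param census Data frame with `zone` and `area_1e4ha` columns (census
#'   areas in 10^4 ha); an optional `level` column is filtered with
#'   `level`.
#' @param level Optional census level tag to filter on.
#' @param exclude Zone ids to exclude from the comparison.
#' @return List with `summary` (per map: `map`, `n_zones`, `r2`,
#'   `pearson_r2`, `rmse_1e4ha`, `total_bias_1e4ha`) and `detail` (tidy
#'   per-map, per-zone mapped vs census areas for scatter plotting).
#' @export
compare_table <- function(maps, zones, census, level = NULL, exclude = NULL) {
  stopifnot(is.list(maps), length(maps) >= 1, !is.null(names(maps)))
  if (!is.null(level) && "level" %in% names(census))
    census <- census[census$level == level, , drop = FALSE]
  detail_list <- list(); summ <- list()
  for (nm in names(maps)) {
    za <- zonal_area(maps[[nm]], zones)
    joined <- merge(za, census[, c("zone", "area_1e4ha")],
                    by = "zone", suffixes = c("_mapped", "_census"))
    unmatched <- setdiff(union(za$zone, census$zone), joined$zone)
    if (length(unmatched))
      warning("zones without a census/map match: ",
              paste(unmatched, collapse = ", "))
    joined <- joined[!joined$zone %in% exclude, , drop = FALSE]
    x <- joined$area_1e4ha_mapped; y <- joined$area_1e4ha_census
    summ[[nm]] <- data.frame(
      map = nm, n_zones = nrow(joined),
      r2 = r2_agreement(x, y),
      pearson_r2 = if (stats::sd(x) > 0 && stats::sd(y) > 0)
        stats::cor(x, y)^2 else NA_real_,
      rmse_1e4ha = rmse(x, y),
      total_bias_1e4ha = sum(x - y))
    detail_list[[nm]] <- data.frame(map = nm, joined)
  }
  out <- list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
              detail = do.call(rbind, c(detail_list, make.row.names = FALSE)))
  out
}
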