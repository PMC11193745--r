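# End-to-end pipeline: harmonize -> vote -> sweep -> select -> refined map
# -> accuracy reports -> area comparison, with an auditable run log.

metric_row <- function(name, cm) {
  m <- metrics(cm)
  data.frame(map = name, TP = cm$TP, FP = cm$FP, FN = cm$FN, TN = cm$TN,
             OA = m$OA, PA = m$PA, UA = m$UA, OE = m$OE, CE = m$CE,
             F1 = m$F1, MCC = m$MCC)
}

load_products <- function(product_cfg, nodata_code = 255L) {
  maps <- list()
  for (i in seq_along(product_cfg)) {
    p <- product_cfg[[i]]
    nm <- if (!is.null(p$name)) p$name else
      tools::file_path_sans_ext(basename(p$path))
    r <- read_raster(p$path)
    cmap <- class_map(nm,
                      cropland_codes = if (!is.null(p$cropland_codes))
                        unlist(p$cropland_codes) else 1L,
                      nodata_codes = if (!is.null(p$nodata_codes))
                        unlist(p$nodata_codes) else
                          if (!is.na(r$nodata)) r$nodata else integer())
    maps[[nm]] <- binarize(r$values, cmap, r$spec, nodata_code = nodata_code)
  }
  for (g in maps[-1]) stop_if_misaligned(maps[[1]]$spec, g$spec, "products")
  maps
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

#' Run the full refinement pipeline from a configuration
#'
#' Executes the whole workflow on file inputs: load and binarize the
#' product rasters, build the vote map, sweep and select the consensus
#' threshold against the reference sample and census total, and emit the
#' artifact bundle: vote and refined GeoTIFFs, the sweep CSV, per-map and
#' refined accuracy CSV (raw and design-adjusted), commission/omission
#' error samples, the zonal area comparison, and a JSON run log with the
#' config echo, seed and package version. Each stage is logged; a failing
#' stage aborts with the stage name.
#'
#' @param config A YAML file path or list with entries: `products` (list of
#'   `{path, cropland_codes, nodata_codes, name}`), `samples` (`{path,
#'   label_map, col_map}` or a data frame), `census_total` (10^4 ha) and/or
#'   `census` (`{path}` CSV with `zone`, `area_1e4ha`), optional `zones`
#'   (`{path}` zone raster), `rule`, `f1_tie_epsilon`, `nodata_policy`,
#'   `seed`.
#' @param out_dir Output directory for the artifact bundle.
#' @return Invisibly, a list with `vote`, `refined`, `sweep`, `threshold`,
#'   `metrics`, `adjusted`, `area_comparison`, `log`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(package = "cropconsensus",
              version = as.character(utils::packageVersion("cropconsensus")),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              seed = config$seed, config = config)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  maps <- stage("harmonize", load_products(config$products))
  samples <- stage("samples", {
    if (is.data.frame(config$samples)) config$samples
    else do.call(read_samples_csv, c(list(path = config$samples$path),
      config$samples[intersect(names(config$samples),
                               c("label_map", "col_map"))]))
  })
  zones <- NULL; census <- NULL
  if (!is.null(config$zones)) zones <- stage("zones", {
    zr <- read_raster(config$zones$path)
    z <- zr$values
    if (!is.na(zr$nodata)) z[z == zr$nodata] <- NA_integer_
    zone_grid(zr$spec, z)
  })
  if (!is.null(config$census)) census <- stage("census",
    utils::read.csv(config$census$path))
  census_total <- if (!is.null(config$census_total)) config$census_total
    else if (!is.null(census)) sum(census$area_1e4ha)
    else stop("config needs census_total or a census table")

  rule <- if (!is.null(config$rule)) config$rule else "f1-then-bias"
  eps <- if (!is.null(config$f1_tie_epsilon)) config$f1_tie_epsilon else 0
  npol <- if (!is.null(config$nodata_policy)) config$nodata_policy
    else "zero-vote"
  res <- stage("refine",
    refine(maps, samples, census_total, rule = rule, f1_tie_epsilon = eps,
           nodata_policy = npol))

  acc <- stage("accuracy", {
    rows <- lapply(names(maps), function(nm)
      metric_row(nm, confusion_from_samples(maps[[nm]], samples,
                                            quiet = TRUE)))
    rows <- c(rows, list(metric_row(
      sprintf("refined_t%02d", res$threshold),
      confusion_from_samples(res$refined, samples, quiet = TRUE))))
    do.call(rbind, rows)
  })
  adj <- stage("adjusted", {
    valid <- sum(res$refined$labels != res$refined$nodata_code)
    total_area <- valid * res$refined$spec$pixel_size^2 / 1e8
    adjusted_estimates(accuracy_design(res$refined, samples), total_area)
  })
  errs <- stage("error-samples", error_samples(res$refined, samples))
  area_cmp <- NULL
  if (!is.null(zones) && !is.null(census))
    area_cmp <- stage("area-comparison", {
      all_maps <- c(maps, stats::setNames(list(res$refined),
                                          sprintf("refined_t%02d",
                                                  res$threshold)))
      compare_table(all_maps, zones, census,
                    exclude = unlist(config$exclude_zones))
    })

  stage("write", {
    vt <- res$vote$votes
    vt[is.na(vt)] <- 255L
    write_geotiff_uint8(vt, res$vote$spec, file.path(out_dir, "vote.tif"),
                        nodata = 255L)
    write_label_grid(res$refined, file.path(out_dir, "refined.tif"))
    utils::write.csv(res$sweep, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(acc, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    write_samples_csv(errs, file.path(out_dir, "error_samples.csv"))
    if (!is.null(area_cmp)) {
      utils::write.csv(area_cmp$summary,
                       file.path(out_dir, "area_comparison.csv"),
                       row.names = FALSE)
      utils::write.csv(area_cmp$detail,
                       file.path(out_dir, "area_comparison_zones.csv"),
                       row.names = FALSE)
    }
    log$selected_threshold <- res$threshold
    log$n_samples <- nrow(samples)
    log$n_error_samples <- nrow(errs)
    log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(list(vote = res$vote, refined = res$refined, sweep = res$sweep,
                 threshold = res$threshold, metrics = acc, adjusted = adj,
                 error_samples = errs, area_comparison = area_cmp,
                 log = log))
}

#' Score a single external map against a reference sample
#'
#' The single-map counterpart of [run_pipeline()]: raw metric set,
#' design-adjusted estimates and commission/omission samples for one map,
#' without any consensus step.
#'
#' @param map A [label_grid()] or a GeoTIFF path of an already-binary map.
#' @param samples A labeled sample-pool data frame.
#' @param zones Optional [zone_grid()] for per-zone metrics.
#' @param total_area Total valid map area in 10^4 ha; defaults to the
#'   map's non-nodata area.
#' @return List with `metrics` (one-row data frame in the sweep schema),
#'   `adjusted`, `error_samples` and optional `per_zone`.
#' @export
validate_only <- function(map, samples, zones = NULL, total_area = NULL) {
  if (is.character(map)) map <- read_label_grid(map)
  stopifnot(inherits(map, "label_grid"))
  cm <- confusion_from_samples(map, samples, quiet = TRUE)
  if (is.null(total_area))
    total_area <- sum(map$labels != map$nodata_code) *
      map$spec$pixel_size^2 / 1e8
  out <- list(metrics = metric_row("map", cm),
              adjusted = adjusted_estimates(accuracy_design(map, samples),
                                            total_area),
              error_samples = error_samples(map, samples))
  if (!is.null(zones)) out$per_zone <- per_zone_metrics(map, samples, zones)
  out
}
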