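# Synthetic test worlds: spatially autocorrelated binary truth, K product
# maps corrupted by stated omission/commission rates, a zone partition,
# census areas derived from the truth, and sample pools. Everything is
# deterministic under (params, seed).

#' Parameters of a synthetic cropland scene
#'
#' Defaults describe the reference study conditions used throughout the
#' test suite: a 512 x 512 grid of 30 m pixels, 30% cropland with a truth
#' correlation length of 8 pixels (fragmented parcels), K = 10 product maps
#' with omission rate 0.2 and commission rate 0.1, spatially independent
#' errors, 9 zones and an exact (noise-free) census.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param pixel_size Pixel edge length in metres (30 m by default).
#' @param cropland_fraction Target cropland share of the truth, in (0, 1).
#' @param truth_corr_len Correlation length of the truth field in pixels;
#'   0 gives an i.i.d. Bernoulli field.
#' @param k_maps Number of product maps, K >= 2.
#' @param omission,commission Per-map flip rates in `[0, 0.5)`; recycled to
#'   length K. Omission flips truth-cropland to non-cropland, commission the
#'   reverse, so a map's expected producer's accuracy against truth is
#'   `1 - omission`.
#' @param error_corr_len Correlation length of the error fields in pixels;
#'   0 = independent errors.
#' @param n_zones Number of zones in the rectangular-block partition.
#' @param census_noise_sd SD of multiplicative census noise; 0 makes census
#'   areas exact functionals of the truth.
#' @param crs_tag CRS tag shared by all scene grids.
#' @param seed Master seed; spawns per-component substreams so that truth,
#'   each map and the census can be varied independently.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(n_rows = 512, n_cols = 512, pixel_size = 30,
                         cropland_fraction = 0.3, truth_corr_len = 8,
                         k_maps = 10, omission = 0.2, commission = 0.1,
                         error_corr_len = 0, n_zones = 9,
                         census_noise_sd = 0,
                         crs_tag = "synthetic-equal-area", seed = 1L) {
  if (cropland_fraction <= 0 || cropland_fraction >= 1)
    stop("cropland_fraction must be in (0, 1)")
  if (k_maps < 2) stop("k_maps must be >= 2")
  omission <- rep_len(omission, k_maps)
  commission <- rep_len(commission, k_maps)
  if (any(omission < 0 | omission >= 0.5 | commission < 0 | commission >= 0.5))
    stop("omission/commission rates must be in [0, 0.5)")
  if (n_zones > n_rows * n_cols) stop("more zones than cells")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_size = pixel_size,
                 cropland_fraction = cropland_fraction,
                 truth_corr_len = truth_corr_len, k_maps = as.integer(k_maps),
                 omission = omission, commission = commission,
                 error_corr_len = error_corr_len,
                 n_zones = as.integer(n_zones),
                 census_noise_sd = census_noise_sd, crs_tag = crs_tag,
                 seed = as.integer(seed)),
            class = "scene_params")
}

scene_spec <- function(params) {
  grid_spec(0, params$n_rows * params$pixel_size, params$pixel_size,
            params$n_rows, params$n_cols, params$crs_tag)
}

# moving-average along columns with edge replication
box_pass_cols <- function(M, r) {
  nr <- nrow(M)
  Mp <- rbind(M[rep(1L, r), , drop = FALSE], M, M[rep(nr, r), , drop = FALSE])
  cs <- rbind(0, apply(Mp, 2, cumsum))
  (cs[(1:nr) + 2L * r + 1L, , drop = FALSE] - cs[1:nr, , drop = FALSE]) /
    (2 * r + 1)
}

# separable box blur, `passes` repetitions approximate a Gaussian kernel
box_blur <- function(M, r, passes = 3L) {
  r <- as.integer(max(1, round(r)))
  for (i in seq_len(passes)) M <- t(box_pass_cols(t(box_pass_cols(M, r)), r))
  M
}

# a spatially correlated field rank-transformed to uniform marginals
correlated_uniform <- function(nr, nc, corr_len) {
  z <- matrix(stats::runif(nr * nc), nr, nc)
  if (corr_len <= 0) return(z)
  z <- box_blur(z, corr_len)
  matrix(rank(z, ties.method = "first") / (nr * nc + 1), nr, nc)
}

#' Generate a spatially autocorrelated binary truth map
#'
#' Smooths a seeded white-noise field with a repeated box kernel of the
#' stated correlation length and thresholds it at the quantile that yields
#' the target cropland fraction (exact to one cell); with correlation
#' length 0 the field is i.i.d. Bernoulli(`cropland_fraction`).
#'
#' @param params A [scene_params()].
#' @param seed Optional seed overriding `params$seed`.
#' @return A [label_grid()].
#' @export
generate_truth <- function(params, seed = params$seed) {
  spec <- scene_spec(params)
  run_seeded(seed, {
    nr <- params$n_rows; nc <- params$n_cols
    if (params$truth_corr_len <= 0) {
      lab <- matrix(as.integer(stats::runif(nr * nc) <
                                 params$cropland_fraction), nr, nc)
    } else {
      z <- box_blur(matrix(stats::runif(nr * nc), nr, nc),
                    params$truth_corr_len)
      k <- round(params$cropland_fraction * nr * nc)
      th <- sort(as.vector(z), decreasing = TRUE)[k]
      lab <- matrix(0L, nr, nc)
      lab[z >= th] <- 1L
    }
    label_grid(spec, lab)
  })
}

#' Corrupt a truth map with omission and commission errors
#'
#' Truth-cropland cells flip to non-cropland with probability `o` and
#' truth-non-cropland cells flip to cropland with probability `c`,
#' independently per cell, or driven by a thresholded spatially correlated
#' field when `error_corr_len > 0` (patchy, product-like errors with the
#' same marginal rates). Nodata passes through.
#'
#' @param truth A [label_grid()].
#' @param o,c Omission and commission rates in `[0, 0.5)`.
#' @param error_corr_len Error-field correlation length in pixels.
#' @param seed Integer seed.
#' @return A [label_grid()] with expected producer's accuracy `1 - o` and
#'   per-cell false-positive rate `c` against `truth`.
#' @export
corrupt_map <- function(truth, o, c, error_corr_len = 0, seed = NULL) {
  stopifnot(inherits(truth, "label_grid"))
  run_seeded(seed, {
    nr <- truth$spec$n_rows; nc <- truth$spec$n_cols
    u <- correlated_uniform(nr, nc, error_corr_len)
    v <- correlated_uniform(nr, nc, error_corr_len)
    lab <- truth$labels
    lab[truth$labels == 1L & u < o] <- 0L
    lab[truth$labels == 0L & v < c] <- 1L
    label_grid(truth$spec, lab, nodata_code = truth$nodata_code)
  })
}

#' Partition the grid into rectangular zones
#'
#' Splits the grid into `n_zones` contiguous rectangular blocks (the factor
#' pair of `n_zones` closest to the grid aspect), numbered row-major. A
#' coarser grouping — one group per block-row, the "province" level — is
#' attached for multi-level comparisons.
#'
#' @param params A [scene_params()].
#' @return A [zone_grid()] with a `group` mapping.
#' @export
generate_zones <- function(params) {
  spec <- scene_spec(params)
  nz <- params$n_zones
  divs <- which(nz %% seq_len(nz) == 0)
  nz_r <- max(divs[divs <= sqrt(nz)])
  nz_c <- nz %/% nz_r
  rb <- rep(seq_len(nz_r), times = diff(round(seq(0, spec$n_rows,
                                                  length.out = nz_r + 1))))
  cb <- rep(seq_len(nz_c), times = diff(round(seq(0, spec$n_cols,
                                                  length.out = nz_c + 1))))
  z <- outer(rb, cb, function(a, b) (a - 1L) * nz_c + b)
  storage.mode(z) <- "integer"
  zone_grid(spec, z,
            group = data.frame(zone = seq_len(nz),
                               group = rep(seq_len(nz_r), each = nz_c)))
}

#' Generate a complete synthetic scene
#'
#' Composes truth, K corrupted product maps, the zone partition, and a
#' census table equal to the truth's zonal areas times `1 + eps` with
#' `eps ~ N(0, census_noise_sd)`. The master seed spawns independent
#' substreams for the truth, each map and the census noise.
#'
#' @param params A [scene_params()].
#' @return An object of class `synthetic_scene`: list with `truth`,
#'   `products` (list of K [label_grid()]s), `zones`, `census` (data frame
#'   `zone`, `area_1e4ha`), and `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  subseeds <- run_seeded(params$seed,
                         sample.int(.Machine$integer.max, params$k_maps + 2L))
  truth <- generate_truth(params, seed = subseeds[1])
  products <- lapply(seq_len(params$k_maps), function(k)
    corrupt_map(truth, params$omission[k], params$commission[k],
                error_corr_len = params$error_corr_len,
                seed = subseeds[1L + k]))
  zones <- generate_zones(params)
  census <- zonal_area(truth, zones)
  if (params$census_noise_sd > 0) {
    eps <- run_seeded(subseeds[params$k_maps + 2L],
                      stats::rnorm(nrow(census), 0, params$census_noise_sd))
    census$area_1e4ha <- census$area_1e4ha * (1 + eps)
  }
  structure(list(truth = truth, products = products, zones = zones,
                 census = census, params = params),
            class = "synthetic_scene")
}

#' Write a synthetic scene to a directory
#'
#' Emits `truth.tif`, `product_XX.tif`, `zones.tif` (zone ids; requires
#' fewer than 255 zones for the uint8 writer), `census.csv` and a
#' `params.yaml` sidecar echoing the generator parameters, so a scene can
#' be consumed by the file-based pipeline and reproduced from its
#' provenance record.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_grid(scene$truth, file.path(dir, "truth.tif"))
  for (k in seq_along(scene$products))
    write_label_grid(scene$products[[k]],
                     file.path(dir, sprintf("product_%02d.tif", k)))
  if (max(scene$zones$zones, na.rm = TRUE) > 254)
    stop("uint8 zone writer supports at most 254 zones")
  write_geotiff_uint8(scene$zones$zones, scene$zones$spec,
                      file.path(dir, "zones.tif"), nodata = 255L)
  utils::write.csv(scene$census, file.path(dir, "census.csv"),
                   row.names = FALSE)
  p <- scene$params; class(p) <- NULL
  yaml::write_yaml(p, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read a scene directory back
#'
#' @param dir A directory written by [write_scene()].
#' @return A `synthetic_scene` (params restored from the sidecar).
#' @export
read_scene <- function(dir) {
  params <- do.call(scene_params, yaml::read_yaml(file.path(dir, "params.yaml")))
  truth <- read_label_grid(file.path(dir, "truth.tif"))
  prod_files <- sort(list.files(dir, "^product_[0-9]+\\.tif$",
                                full.names = TRUE))
  products <- lapply(prod_files, read_label_grid)
  zr <- read_raster(file.path(dir, "zones.tif"))
  zones <- zone_grid(zr$spec, zr$values)
  census <- utils::read.csv(file.path(dir, "census.csv"))
  structure(list(truth = truth, products = products, zones = zones,
                 census = census, params = params),
            class = "synthetic_scene")
}

#' End-to-end parameter recovery over repeated scenes
#'
#' The acceptance harness: for each replicate, generate a scene, draw a
#' stratified reference sample on the vote map, label it from the truth,
#' run the full refinement, and record the selected threshold, the refined
#' map's full-grid F1 against truth, the mean single-product F1, and the
#' design-based cropland-area estimate with its CI against the true area.
#'
#' @param params A [scene_params()]; each replicate uses
#'   `params$seed + rep - 1` unless `seeds` is given.
#' @param n_reps Number of replicates.
#' @param n_samples Reference-sample size per replicate.
#' @param seeds Optional explicit seed vector of length `n_reps`.
#' @return List with `results` (one row per replicate: `seed`,
#'   `threshold`, `refined_f1`, `mean_product_f1`, `area_est_1e4ha`,
#'   `area_truth_1e4ha`, `ci_covers`) and `summary` (means/SDs, interior
#'   threshold share, CI coverage).
#' @export
parameter_recovery_suite <- function(params, n_reps = 20, n_samples = 1500,
                                     seeds = NULL) {
  stopifnot(inherits(params, "scene_params"))
  if (is.null(seeds)) seeds <- params$seed + seq_len(n_reps) - 1L
  stopifnot(length(seeds) == n_reps)
  total_area <- params$n_rows * params$n_cols * params$pixel_size^2 / 1e8
  rows <- lapply(seq_len(n_reps), function(i) {
    p <- params; p$seed <- as.integer(seeds[i])
    scene <- generate_scene(p)
    vote <- vote_map(scene$products)
    pts <- stratified_sample(vote, n_samples, restrict_to_extent = FALSE,
                             min_per_stratum = 2L, seed = seeds[i] + 10000L)
    pts <- label_from_truth(pts, scene$truth)
    res <- refine(scene$products, pts, sum(scene$census$area_1e4ha))
    ref_f1 <- metrics(confusion_grids(res$refined, scene$truth))$F1
    prod_f1 <- vapply(scene$products, function(m)
      metrics(confusion_grids(m, scene$truth))$F1, 0)
    est <- adjusted_estimates(accuracy_design(res$refined, pts), total_area)
    truth_area <- mapped_area(scene$truth)
    data.frame(seed = seeds[i], threshold = res$threshold,
               refined_f1 = ref_f1, mean_product_f1 = mean(prod_f1),
               area_est_1e4ha = est$area_1e4ha[["1"]],
               area_truth_1e4ha = truth_area,
               ci_covers = est$ci_lower_1e4ha[["1"]] <= truth_area &&
                 truth_area <= est$ci_upper_1e4ha[["1"]])
  })
  results <- do.call(rbind, rows)
  k <- params$k_maps
  list(results = results,
       summary = list(
         mean_refined_f1 = mean(results$refined_f1),
         mean_product_f1 = mean(results$mean_product_f1),
         interior_threshold_share =
           mean(results$threshold > 1 & results$threshold < k),
         ci_coverage = mean(results$ci_covers),
         mean_area_bias_1e4ha =
           mean(results$area_est_1e4ha - results$area_truth_1e4ha)))
}
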