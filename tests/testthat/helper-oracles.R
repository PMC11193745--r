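# Independent oracles and small fixtures used across the suite.

# Metric oracle: rebuilds the binary prediction/reference vectors from the
# counts and derives every metric from first principles (MCC as the Pearson
# correlation of the two binary vectors), never touching the package's
# closed-form arithmetic.
oracle_metrics <- function(TP, FP, FN, TN) {
  ref <- c(rep(1, TP), rep(0, FP), rep(1, FN), rep(0, TN))
  map <- c(rep(1, TP), rep(1, FP), rep(0, FN), rep(0, TN))
  OA <- mean(ref == map)
  PA <- if (sum(ref == 1) > 0) mean(map[ref == 1] == 1) else 0
  UA <- if (sum(map == 1) > 0) mean(ref[map == 1] == 1) else 0
  F1 <- if (PA + UA > 0) 2 * PA * UA / (PA + UA) else 0
  MCC <- suppressWarnings(stats::cor(ref, map))
  if (is.na(MCC)) MCC <- 0
  list(OA = OA, PA = PA, UA = UA, OE = 1 - PA, CE = 1 - UA, F1 = F1,
       MCC = MCC)
}

# Brute-force confusion tally: explicit per-sample loop with its own
# point-in-pixel arithmetic.
brute_confusion <- function(grid, samples) {
  TP <- FP <- FN <- TN <- 0
  for (i in seq_len(nrow(samples))) {
    col <- floor((samples$x[i] - grid$spec$origin_x) / grid$spec$pixel_size) + 1
    row <- floor((grid$spec$origin_y - samples$y[i]) / grid$spec$pixel_size) + 1
    if (row < 1 || row > grid$spec$n_rows || col < 1 || col > grid$spec$n_cols)
      next
    m <- grid$labels[row, col]
    if (m == grid$nodata_code) next
    r <- samples$label[i]
    if (r == 1 && m == 1) TP <- TP + 1
    else if (r == 0 && m == 1) FP <- FP + 1
    else if (r == 1 && m == 0) FN <- FN + 1
    else TN <- TN + 1
  }
  list(TP = TP, FP = FP, FN = FN, TN = TN)
}

# tiny deterministic label grid from a matrix literal
lg <- function(m, pixel = 30, crs = "aea", nodata = 255L) {
  m <- as.matrix(m); storage.mode(m) <- "integer"
  label_grid(grid_spec(0, nrow(m) * pixel, pixel, nrow(m), ncol(m), crs),
             m, nodata_code = nodata)
}

# small standard scene used by several files
small_scene <- function(seed = 42, n = 96, k = 6) {
  generate_scene(scene_params(n_rows = n, n_cols = n, k_maps = k,
                              truth_corr_len = 4, n_zones = 4, seed = seed))
}

# the published per-threshold F1 scores of the ten-map sweep
published_f1 <- c(0.470, 0.565, 0.607, 0.644, 0.663, 0.651, 0.566, 0.443,
                  0.270, 0.116)

published_sweep <- function() {
  data.frame(threshold = 1:10, F1 = published_f1,
             census_bias_1e4ha = NA_real_)
}
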