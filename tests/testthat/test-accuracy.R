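test_that("metrics reproduce the reference confusion-matrix arithmetic", {
  # matrix reconstructed from the published threshold-5 row (PA 0.698,
  # UA 0.632) and the sample totals 2,022 / 13,843
  m <- metrics(confusion_counts(TP = 1411, FP = 822, FN = 611, TN = 13021))
  expect_equal(round(m$OA, 3), 0.910)
  expect_equal(round(m$PA, 3), 0.698)
  expect_equal(round(m$UA, 3), 0.632)
  expect_equal(round(m$F1, 3), 0.663)
  expect_equal(round(m$MCC, 3), 0.612)
  expect_equal(m$OE, 1 - m$PA)
  expect_equal(m$CE, 1 - m$UA)
})

test_that("metrics handle perfect and degenerate matrices by convention", {
  p <- metrics(confusion_counts(7, 0, 0, 13))
  expect_equal(unlist(p[c("OA", "PA", "UA", "F1", "MCC")]),
               c(OA = 1, PA = 1, UA = 1, F1 = 1, MCC = 1))
  d <- metrics(confusion_counts(0, 0, 5, 10))
  expect_equal(d$PA, 0); expect_equal(d$F1, 0); expect_equal(d$MCC, 0)
  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "all-zero")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("metrics agree with an independent re-derivation on random matrices", {
  set.seed(77)
  for (i in 1:1000) {
    cnt <- stats::rmultinom(1, sample(8:400, 1), prob = stats::runif(4))[, 1]
    if (sum(cnt) == 0) next
    m <- metrics(confusion_counts(cnt[1], cnt[2], cnt[3], cnt[4]))
    o <- oracle_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    for (f in c("OA", "PA", "UA", "OE", "CE", "F1", "MCC"))
      expect_lt(abs(m[[f]] - o[[f]]), 1e-12)
  }
})

test_that("MCC and OA are invariant under class swap, PA/UA swap under transpose", {
  set.seed(31)
  for (i in 1:50) {
    cnt <- sample(1:200, 4)
    a <- metrics(confusion_counts(cnt[1], cnt[2], cnt[3], cnt[4]))
    sw <- metrics(confusion_counts(cnt[4], cnt[3], cnt[2], cnt[1]))
    expect_equal(a$MCC, sw$MCC)
    expect_equal(a$OA, sw$OA)
    tr <- metrics(confusion_counts(cnt[1], cnt[3], cnt[2], cnt[4]))
    expect_equal(a$PA, tr$UA)
    expect_equal(a$UA, tr$PA)
  }
})

test_that("confusion_from_samples applies the point-in-pixel rule and drops nodata", {
  g <- lg(matrix(c(1, 0, 255, 0), 2, 2))
  # single sample at the center of pixel (1,1), reference 1, map 1
  s <- sample_pool(15, 45, label = 1)
  cm <- confusion_from_samples(g, s, quiet = TRUE)
  expect_equal(c(cm$TP, cm$FP, cm$FN, cm$TN), c(1, 0, 0, 0))
  # all-1 map, reference all 0 -> pure commission
  allone <- lg(matrix(1, 5, 5))
  s2 <- sample_pool(runif(10, 0, 150), runif(10, 0, 150), label = 0)
  cm2 <- confusion_from_samples(allone, s2, quiet = TRUE)
  expect_equal(cm2$FP, 10)
  # nodata and out-of-extent samples are dropped with counts
  s3 <- sample_pool(c(15, 45, 1e5), c(45, 45, 15), label = c(1, 1, 1))
  expect_message(cm3 <- confusion_from_samples(g, s3), "dropped 1.*1")
  expect_equal(attr(cm3, "dropped_outside"), 1)
  expect_equal(attr(cm3, "dropped_nodata"), 1)
  expect_error(confusion_from_samples(g, sample_pool(1e5, 1e5, 1),
                                      quiet = TRUE), "no usable")
})

test_that("confusion matches the brute-force per-sample loop on a synthetic scene", {
  sc <- small_scene(seed = 14)
  map <- sc$products[[1]]
  set.seed(3)
  ext <- map$spec$pixel_size * map$spec$n_cols
  s <- sample_pool(runif(400, -50, ext + 50), runif(400, -50, ext + 50),
                   label = sample(0:1, 400, TRUE))
  cm <- confusion_from_samples(map, s, quiet = TRUE)
  bf <- brute_confusion(map, s)
  expect_equal(c(cm$TP, cm$FP, cm$FN, cm$TN),
               c(bf$TP, bf$FP, bf$FN, bf$TN))
})

test_that("stratified adjusted estimates match hand computation", {
  # 2 strata = map classes, W = (0.3, 0.7), n = 50 each, diagonals 40/45:
  # cropland stratum (map 1) has 40 correct, non-cropland stratum 45
  design <- data.frame(stratum = c(1, 0), map_class = c(1, 0),
                       W = c(0.3, 0.7), n_ref0 = c(10, 45),
                       n_ref1 = c(40, 5))
  est <- adjusted_estimates(design, total_area = 100)
  expect_equal(est$OA, 0.3 * 0.8 + 0.7 * 0.9)
  expect_equal(est$p_area[["1"]], 0.3 * (40 / 50) + 0.7 * (5 / 50))
  expect_equal(est$area_1e4ha[["1"]], 0.31 * 100)
  expect_equal(sum(est$p_area), 1)
  # SE per the stratified variance estimator
  se_hand <- sqrt(0.3^2 * 0.8 * 0.2 / 49 + 0.7^2 * 0.1 * 0.9 / 49)
  expect_equal(est$p_area_se[["1"]], se_hand)
  expect_equal(est$ci_upper_1e4ha[["1"]] - est$area_1e4ha[["1"]],
               1.96 * se_hand * 100)
  # degenerate single stratum: adjusted equals raw
  one <- data.frame(stratum = 1, map_class = 1, W = 1, n_ref0 = 20,
                    n_ref1 = 80)
  expect_equal(adjusted_estimates(one, 10)$p_area[["1"]], 0.8)
  expect_error(adjusted_estimates(
    data.frame(stratum = 1, map_class = 1, W = 0.9, n_ref0 = 5, n_ref1 = 5),
    10), "sum to 1")
  expect_error(adjusted_estimates(
    data.frame(stratum = c(0, 1), map_class = c(0, 1), W = c(0.5, 0.5),
               n_ref0 = c(1, 0), n_ref1 = c(0, 1)), 10), "n_i >= 2")
})

test_that("equal-weight design reduces adjusted OA to raw OA exactly", {
  sc <- small_scene(seed = 15)
  map <- sc$products[[2]]
  v <- vote_map(sc$products)
  pts <- label_from_truth(
    stratified_sample(v, 400, restrict_to_extent = FALSE,
                      min_per_stratum = 2L, seed = 8), sc$truth)
  d <- accuracy_design(map, pts)
  n_i <- tapply(d$n_ref0 + d$n_ref1, d$stratum, sum)
  d$W <- as.numeric(n_i[as.character(d$stratum)] / sum(n_i))
  est <- adjusted_estimates(d, 1)
  raw <- metrics(confusion_from_samples(map, pts, quiet = TRUE))
  expect_equal(est$OA, raw$OA)
})

test_that("per-zone metrics partition the samples and keep empty zones flagged", {
  sc <- small_scene(seed = 16)
  map <- sc$products[[1]]
  pts <- label_from_truth(
    stratified_sample(vote_map(sc$products), 300,
                      restrict_to_extent = FALSE, min_per_stratum = 1L,
                      seed = 4), sc$truth)
  # single all-covering zone equals global metrics
  allz <- zone_grid(map$spec, matrix(1L, map$spec$n_rows, map$spec$n_cols))
  pz <- per_zone_metrics(map, pts, allz)
  glob <- metrics(confusion_from_samples(map, pts, quiet = TRUE))
  expect_equal(pz$OA[1], glob$OA)
  expect_equal(pz$F1[1], glob$F1)
  # zone confusions sum to the pooled confusion
  pz4 <- per_zone_metrics(map, pts, sc$zones)
  gcm <- confusion_from_samples(map, pts, quiet = TRUE)
  expect_equal(sum(pz4$TP, na.rm = TRUE), gcm$TP)
  expect_equal(sum(pz4$FN, na.rm = TRUE), gcm$FN)
  expect_identical(nrow(pz4), 4L)
})

test_that("error samples are exactly the FP (commission) and FN (omission) points", {
  sc <- small_scene(seed = 17)
  map <- sc$products[[1]]
  pts <- label_from_truth(
    stratified_sample(vote_map(sc$products), 300,
                      restrict_to_extent = FALSE, min_per_stratum = 1L,
                      seed = 5), sc$truth)
  es <- error_samples(map, pts)
  cm <- confusion_from_samples(map, pts, quiet = TRUE)
  expect_equal(sum(es$error == "commission"), cm$FP)
  expect_equal(sum(es$error == "omission"), cm$FN)
  # perfect map -> no error samples
  expect_identical(nrow(error_samples(sc$truth, pts)), 0L)
  # all-1 map: exactly the reference-0 samples, tagged commission
  allone <- lg(matrix(1, map$spec$n_rows, map$spec$n_cols))
  allone$spec <- map$spec
  es2 <- error_samples(allone, pts)
  expect_equal(nrow(es2), sum(pts$label == 0))
  expect_true(all(es2$error == "commission"))
})

test_that("stratified area estimator is unbiased with nominal CI coverage", {
  # fixed scene, known truth area; repeated stratified redraws
  p <- scene_params(n_rows = 160, n_cols = 160, k_maps = 2,
                    truth_corr_len = 4, seed = 404)
  sc <- generate_scene(p)
  map <- sc$products[[1]]
  truth_area <- mapped_area(sc$truth)
  total_area <- 160 * 160 * 900 / 1e8
  idx1 <- which(map$labels == 1L); idx0 <- which(map$labels == 0L)
  n <- 400
  n1 <- round(n * length(idx1) / (length(idx1) + length(idx0)))
  set.seed(2024)
  est_area <- ci_lo <- ci_hi <- numeric(300)
  for (r in 1:300) {
    cells <- c(sample(idx1, n1), sample(idx0, n - n1))
    rc <- arrayInd(cells, dim(map$labels))
    ctr <- cropconsensus:::cell_center(map$spec, rc[, 1], rc[, 2])
    pts <- label_from_truth(sample_pool(ctr$x, ctr$y), sc$truth)
    est <- adjusted_estimates(accuracy_design(map, pts), total_area)
    est_area[r] <- est$area_1e4ha[["1"]]
    ci_lo[r] <- est$ci_lower_1e4ha[["1"]]; ci_hi[r] <- est$ci_upper_1e4ha[["1"]]
  }
  mc_se <- stats::sd(est_area) / sqrt(300)
  expect_lt(abs(mean(est_area) - truth_area), 2 * mc_se)
  expect_gt(mean(ci_lo <= truth_area & truth_area <= ci_hi), 0.90)
})
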