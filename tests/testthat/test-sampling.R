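test_that("merging the published source pools reproduces the printed total", {
  sizes <- c(gfsad = 1691, aglc = 1296, glance = 2387, stratified = 10491)
  pools <- lapply(seq_along(sizes), function(i) {
    n <- sizes[i]
    # non-colliding coordinates: each pool on its own offset lattice
    sample_pool(x = (seq_len(n) %% 500) * 100 + i * 20,
                y = (seq_len(n) %/% 500) * 100 + i * 20,
                label = rep_len(c(0, 1), n), source = names(sizes)[i])
  })
  merged <- merge_pools(pools, dedup_tolerance = 5)
  expect_identical(nrow(merged), 15865L)
  expect_equal(as.numeric(attr(merged, "provenance")[names(sizes)]),
               as.numeric(sizes))
})

test_that("dedup keeps the first point by pool priority and matches a brute-force oracle", {
  a <- sample_pool(c(0, 100), c(0, 0), label = c(1, 1), source = "a")
  b <- sample_pool(c(3, 200), c(4, 0), label = c(0, 0), source = "b")
  m <- merge_pools(list(a, b), dedup_tolerance = 6)  # (3,4) is 5 away from (0,0)
  expect_identical(nrow(m), 3L)
  expect_true(all(m$source[m$x == 0] == "a"))
  # random pools with planted near-duplicates vs O(n^2) dedup
  set.seed(55)
  n <- 300L
  base <- sample_pool(runif(n, 0, 2000), runif(n, 0, 2000),
                      label = sample(0:1, n, TRUE), source = "p1")
  dup_idx <- sample(n, 60)
  near <- sample_pool(base$x[dup_idx] + runif(60, -8, 8),
                      base$y[dup_idx] + runif(60, -8, 8),
                      label = 1, source = "p2")
  tol <- 15
  m2 <- merge_pools(list(base, near), dedup_tolerance = tol)
  # brute force: scan in order, keep a point iff no kept point is within tol
  pts <- rbind(base[, 1:2], near[, 1:2])
  kept <- integer()
  for (i in seq_len(nrow(pts))) {
    if (!length(kept) ||
        min((pts$x[kept] - pts$x[i])^2 + (pts$y[kept] - pts$y[i])^2) >= tol^2)
      kept <- c(kept, i)
  }
  expect_identical(nrow(m2), length(kept))
  # order-insensitive in size when no duplicates exist
  expect_identical(nrow(merge_pools(list(near, base), dedup_tolerance = 0)),
                   n + 60L)
})

test_that("stratified quotas follow largest-remainder allocation and sum exactly", {
  # strata of sizes 900/100, proportional, n = 100 -> quotas 90/10
  m <- matrix(0L, 100, 10); m[1:90, ] <- 1L  # 900 cells vote 1, 100 vote 0
  v <- vote_map(list(lg(m), lg(m)))          # votes: 900 cells = 2, 100 = 0
  s <- stratified_sample(v, 100, restrict_to_extent = FALSE, seed = 1)
  expect_identical(nrow(s), 100L)
  expect_equal(as.numeric(table(s$stratum)), c(10, 90))
  # every drawn cell's vote matches its stratum and points sit at centers
  cell <- cropconsensus:::point_to_cell(v$spec, s$x, s$y)
  expect_equal(v$votes[cbind(cell$row, cell$col)], s$stratum)
  expect_true(all((s$x - 15) %% 30 == 0))
  # restriction to the maximum cropland extent excludes vote 0
  s2 <- stratified_sample(v, 50, restrict_to_extent = TRUE, seed = 1)
  expect_true(all(s2$stratum >= 1))
  # internal largest-remainder arithmetic
  expect_identical(cropconsensus:::largest_remainder(c(33.4, 33.3, 33.3), 100),
                   c(34L, 33L, 33L))
})

test_that("stratified sampling is reproducible under seed and respects minima", {
  sc <- small_scene(seed = 30)
  v <- vote_map(sc$products)
  a <- stratified_sample(v, 200, min_per_stratum = 3L, seed = 99)
  b <- stratified_sample(v, 200, min_per_stratum = 3L, seed = 99)
  c <- stratified_sample(v, 200, min_per_stratum = 3L, seed = 100)
  expect_identical(a, b)
  expect_false(identical(a$x, c$x))
  expect_true(all(table(a$stratum) >= 3))
  expect_identical(nrow(a), 200L)
  expect_error(stratified_sample(v, 5, min_per_stratum = 3L, seed = 1),
               "infeasible")
  # distinct cells: no pixel center drawn twice within a stratum
  expect_identical(anyDuplicated(a[, c("x", "y")]), 0L)
})

test_that("proportional allocation tracks stratum area shares across draws", {
  sc <- small_scene(seed = 31)
  v <- vote_map(sc$products)
  sizes <- table(v$votes)
  expected <- as.numeric(sizes) / sum(sizes)
  draws <- lapply(1:20, function(s)
    table(factor(stratified_sample(v, 500, restrict_to_extent = FALSE,
                                   seed = s)$stratum,
                 levels = names(sizes))))
  observed <- Reduce(`+`, draws)
  pv <- suppressWarnings(stats::chisq.test(as.numeric(observed),
                                           p = expected)$p.value)
  expect_gt(pv, 0.01)
})

test_that("label_from_truth copies labels by point-in-pixel rule, idempotently", {
  g <- lg(matrix(c(1, 0, 0, 1), 2, 2))
  pts <- sample_pool(c(15, 45), c(45, 45))
  lab <- label_from_truth(pts, g)
  expect_identical(lab$label, c(1L, 0L))
  expect_identical(label_from_truth(lab, g), lab)
  # brute-force lookup comparison on a scene
  sc <- small_scene(seed = 33)
  pts2 <- stratified_sample(vote_map(sc$products), 200,
                            restrict_to_extent = FALSE, seed = 6)
  lab2 <- label_from_truth(pts2, sc$truth)
  for (i in sample(nrow(lab2), 25)) {
    col <- floor(lab2$x[i] / 30) + 1
    row <- floor((sc$truth$spec$origin_y - lab2$y[i]) / 30) + 1
    expect_identical(lab2$label[i], sc$truth$labels[row, col])
  }
  expect_error(label_from_truth(sample_pool(-10, 5), g), "outside")
})

test_that("pool_summary cross-tabulates zone by source with matching totals", {
  sc <- small_scene(seed = 34)
  pts <- label_from_truth(
    stratified_sample(vote_map(sc$products), 300,
                      restrict_to_extent = FALSE, seed = 7), sc$truth)
  pts$source <- rep_len(c("gfsad", "stratified"), nrow(pts))
  tab <- pool_summary(pts, sc$zones)
  tot <- tab[tab$zone == "total", ]
  expect_equal(tot$sum, 300)
  expect_equal(tot$cropland + tot$non_cropland, 300)
  expect_equal(sum(tab$sum[tab$zone != "total"]), 300)
  expect_equal(tot$gfsad + tot$stratified, 300)
  # empty pool
  empty <- pool_summary(sample_pool(numeric(), numeric()))
  expect_equal(empty$sum[empty$zone == "total"], 0)
})

test_that("sample CSV round-trips and accepts the 0/10 label coding", {
  pool <- sample_pool(c(15, 45, 75), c(15, 15, 15), label = c(1, 0, 1),
                      source = "x")
  f <- withr::local_tempfile(fileext = ".csv")
  write_samples_csv(pool, f)
  back <- read_samples_csv(f)
  expect_equal(back$x, pool$x)
  expect_identical(back$label, pool$label)
  # 0/10 coding via the label map
  df <- data.frame(lon = c(1, 2), lat = c(3, 4), land = c(0, 10))
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  got <- read_samples_csv(f2, col_map = list(x = "lon", y = "lat",
                                             label = "land"))
  expect_identical(got$label, c(0L, 1L))
  expect_error(read_samples_csv(f2, label_map = c(`0` = 0, `1` = 1),
                                col_map = list(x = "lon", y = "lat",
                                               label = "land")),
               "unmapped")
})
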