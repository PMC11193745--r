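#' Construct a reference sample pool
#'
#' A sample pool is a plain data frame with numeric `x`, `y`, a binary
#' `label` (1 cropland, 0 non-cropland, `NA` when not yet interpreted) and a
#' `source` provenance tag (e.g. the originating validation library or
#' `"stratified"`). All sampling functions accept and return this shape.
#'
#' @param x,y Point coordinates in map units.
#' @param label Binary labels (or `NA`).
#' @param source Character source tag(s), recycled.
#' @return A `sample_pool` data frame.
#' @export
sample_pool <- function(x, y, label = NA_integer_, source = "unknown") {
  if (any(!is.na(label) & !label %in% c(0, 1)))
    stop("labels must be 0, 1 or NA")
  if (any(!nzchar(source))) stop("source tags must be non-empty")
  n <- length(x)
  out <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    label = rep_len(as.integer(label), n),
                    source = rep_len(as.character(source), n))
  class(out) <- c("sample_pool", "data.frame")
  out
}

#' Merge multi-source sample pools with duplicate removal
#'
#' Concatenates pools in the given order and removes near-duplicate points:
#' when two points lie within `dedup_tolerance` of each other, the one from
#' the earlier pool (or earlier within its pool) survives, so the pool order
#' is the source-priority order. The per-source composition of the merged
#' pool is attached as attribute `"provenance"`.
#'
#' @param pools List of sample-pool data frames sharing one CRS.
#' @param dedup_tolerance Distance below which two points are duplicates,
#'   in map units (conventionally half a pixel).
#' @return A merged `sample_pool` with attribute `"provenance"` (per-source
#'   counts).
#' @export
merge_pools <- function(pools, dedup_tolerance = 15) {
  stopifnot(length(pools) >= 1, all(vapply(pools, is.data.frame, TRUE)))
  all_pts <- do.call(rbind, lapply(pools, function(p)
    p[, c("x", "y", "label", "source")]))
  n <- nrow(all_pts)
  keep <- logical(n)
  if (dedup_tolerance <= 0) {
    keep[] <- TRUE
  } else {
    # spatial-hash dedup: candidates share the same or an adjacent bucket
    cx <- floor(all_pts$x / dedup_tolerance)
    cy <- floor(all_pts$y / dedup_tolerance)
    buckets <- new.env(hash = TRUE, parent = emptyenv())
    tol2 <- dedup_tolerance^2
    for (i in seq_len(n)) {
      dup <- FALSE
      for (dx in -1:1) for (dy in -1:1) {
        key <- paste(cx[i] + dx, cy[i] + dy)
        cand <- buckets[[key]]
        if (!is.null(cand)) {
          d2 <- (all_pts$x[cand] - all_pts$x[i])^2 +
            (all_pts$y[cand] - all_pts$y[i])^2
          if (any(d2 < tol2)) { dup <- TRUE; break }
        }
      }
      if (!dup) {
        keep[i] <- TRUE
        key <- paste(cx[i], cy[i])
        buckets[[key]] <- c(buckets[[key]], i)
      }
    }
  }
  out <- all_pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sample_pool", "data.frame")
  attr(out, "provenance") <- table(out$source)
  attr(out, "n_duplicates_removed") <- n - nrow(out)
  out
}

#' Stratified random sample on vote-map strata
#'
#' Draws pixel centers by stratified random sampling where the strata are
#' the distinct vote values of the consistency map (the finest reading of
#' strata "defined by the proportion of the consistency map"). By default
#' the draw is restricted to the maximum cropland extent (vote >= 1).
#' Per-stratum quotas follow the chosen allocation with largest-remainder
#' rounding, floored at `min_per_stratum`; cells are drawn uniformly without
#' replacement within each stratum and placed at pixel centers. Labels are
#' left `NA` — in a real campaign they come from photo-interpretation, in
#' synthetic mode from [label_from_truth()].
#'
#' @param vote A [vote_map()] result.
#' @param n_total Total number of points to draw.
#' @param allocation `"proportional"` (to stratum cell counts), `"equal"`,
#'   or `"custom"` with `weights`.
#' @param weights Named numeric vector of stratum weights (names = vote
#'   values) for `allocation = "custom"`.
#' @param min_per_stratum Minimum quota for every non-empty stratum.
#' @param restrict_to_extent Restrict strata to vote >= 1 (the maximum
#'   cropland extent).
#' @param seed Integer seed; the draw is reproducible under (inputs, seed).
#' @return A `sample_pool` with `label = NA`, `source = "stratified"` and an
#'   extra `stratum` column (the vote value of the drawn cell).
#' @export
stratified_sample <- function(vote, n_total,
                              allocation = c("proportional", "equal", "custom"),
                              weights = NULL, min_per_stratum = 0L,
                              restrict_to_extent = TRUE, seed = NULL) {
  allocation <- match.arg(allocation)
  stopifnot(inherits(vote, "vote_grid"), n_total >= 1)
  v <- as.vector(vote$votes)
  eligible <- which(!is.na(v) & (!restrict_to_extent | v >= 1L))
  if (!length(eligible)) stop("no eligible cells to sample")
  strat <- v[eligible]
  sizes <- table(strat)
  s_vals <- names(sizes)
  w <- switch(allocation,
    proportional = as.numeric(sizes) / sum(sizes),
    equal = rep(1 / length(sizes), length(sizes)),
    custom = {
      if (is.null(weights) || !all(s_vals %in% names(weights)))
        stop("custom allocation needs a weight for every non-empty stratum")
      ww <- as.numeric(weights[s_vals]); ww / sum(ww)
    })
  quotas <- largest_remainder(n_total * w, n_total)
  # floor at the minimum, then take the excess back from the largest quotas
  if (min_per_stratum > 0) {
    if (n_total < length(sizes) * min_per_stratum)
      stop("infeasible minima: n_total < n_strata * min_per_stratum")
    deficit <- sum(pmax(min_per_stratum - quotas, 0))
    quotas <- pmax(quotas, min_per_stratum)
    while (deficit > 0) {
      i <- which.max(quotas)
      take <- min(deficit, quotas[i] - min_per_stratum)
      quotas[i] <- quotas[i] - take; deficit <- deficit - take
      if (take == 0) break
    }
  }
  if (any(quotas > as.numeric(sizes)))
    stop("stratum smaller than its quota; reduce n_total or adjust allocation")

  run_seeded(seed, {
    picks <- unlist(lapply(seq_along(s_vals), function(i) {
      pool <- eligible[strat == s_vals[i]]
      if (quotas[i] == 0) return(integer())
      pool[sample.int(length(pool), quotas[i])]
    }))
    rc <- arrayInd(picks, c(vote$spec$n_rows, vote$spec$n_cols))
    ctr <- cell_center(vote$spec, rc[, 1], rc[, 2])
    out <- sample_pool(ctr$x, ctr$y, label = NA_integer_,
                       source = "stratified")
    out$stratum <- v[picks]
    out
  })
}

# largest-remainder rounding of real quotas to integers summing to `total`
largest_remainder <- function(q, total) {
  fl <- floor(q)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    extra <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Label sample points from a truth grid
#'
#' Copies labels onto the points by the point-in-pixel rule. This is the
#' synthetic-mode stand-in for photo-interpretation of reference points
#' against very-high-resolution imagery; it is only meaningful when `truth`
#' really is ground truth.
#'
#' @param points A sample-pool data frame (`x`, `y`).
#' @param truth A [label_grid()] covering all points.
#' @return The pool with `label` filled in.
#' @export
label_from_truth <- function(points, truth) {
  stopifnot(inherits(truth, "label_grid"))
  cell <- point_to_cell(truth$spec, points$x, points$y)
  if (anyNA(cell$row)) stop("points outside the truth extent")
  lab <- truth$labels[cbind(cell$row, cell$col)]
  if (any(lab == truth$nodata_code)) stop("points on nodata truth cells")
  points$label <- as.integer(lab)
  points
}

#' Per-zone, per-source composition of a sample pool
#'
#' Cross-tabulates the pool by zone and source, with cropland /
#' non-cropland / total columns; the grand total equals the pool size.
#'
#' @param pool A sample-pool data frame.
#' @param zones Optional [zone_grid()]; when `NULL` a single `"all"` zone is
#'   used.
#' @return Data frame with one row per zone (plus a `"total"` row): counts
#'   per source, `cropland`, `non_cropland`, `sum`.
#' @export
pool_summary <- function(pool, zones = NULL) {
  sources <- sort(unique(pool$source))
  zid <- if (is.null(zones)) rep("all", nrow(pool)) else {
    cell <- point_to_cell(zones$spec, pool$x, pool$y)
    ifelse(is.na(cell$row), "outside",
           as.character(zones$zones[cbind(cell$row, cell$col)]))
  }
  zvals <- if (nrow(pool)) sort(unique(zid)) else character()
  one_row <- function(sel, name) {
    cnt <- vapply(sources, function(s) sum(pool$source[sel] == s), 0)
    data.frame(zone = name, t(cnt),
               cropland = sum(pool$label[sel] == 1, na.rm = TRUE),
               non_cropland = sum(pool$label[sel] == 0, na.rm = TRUE),
               sum = sum(sel), check.names = FALSE)
  }
  rows <- lapply(zvals, function(z) one_row(zid == z, z))
  out <- do.call(rbind, c(rows, list(one_row(rep(TRUE, nrow(pool)), "total"))))
  rownames(out) <- NULL
  out
}

#' Read a sample pool from CSV
#'
#' Reads `x`, `y`, label and source columns, applying a label value map so
#' that external codings (e.g. 0/10 for non-cropland/cropland) are accepted.
#'
#' @param path CSV path.
#' @param label_map Named vector mapping file label values to 0/1; default
#'   identity for 0/1 plus the 0/10 coding used by some deposited sets.
#' @param col_map Named list with the file's column names for `x`, `y`,
#'   `label`, `source` (`source` optional).
#' @return A `sample_pool`.
#' @export
read_samples_csv <- function(path,
                             label_map = c(`0` = 0, `1` = 1, `10` = 1),
                             col_map = list(x = "x", y = "y",
                                            label = "label",
                                            source = "source")) {
  df <- utils::read.csv(path)
  need <- c(col_map$x, col_map$y, col_map$label)
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  lab_raw <- as.character(df[[col_map$label]])
  if (!all(lab_raw %in% names(label_map)))
    stop("unmapped label values: ",
         paste(utils::head(setdiff(lab_raw, names(label_map)), 5), collapse = ", "))
  src <- if (!is.null(col_map$source) && col_map$source %in% names(df))
    df[[col_map$source]] else "file"
  sample_pool(df[[col_map$x]], df[[col_map$y]],
              label = as.integer(label_map[lab_raw]), source = src)
}

#' Write a sample pool to CSV
#'
#' Labels are written in 0/1 coding (1 = cropland).
#'
#' @param pool A sample-pool data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(pool, path) {
  utils::write.csv(pool[, intersect(c("x", "y", "label", "source", "stratum",
                                      "error"), names(pool))],
                   path, row.names = FALSE)
  invisible(path)
}
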