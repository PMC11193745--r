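#' Per-pixel vote (consistency) map across binary cropland maps
#'
#' Counts, for every pixel, how many of the input maps label it cropland.
#' The vote count is the agreement (consistency) statistic that drives the
#' consensus threshold sweep: 0 means no product sees cropland, K means all
#' of them do.
#'
#' Nodata handling is explicit because the products' unobserved areas are
#' not harmonized in practice:
#' * `"zero-vote"` (default): a map's nodata cell contributes no vote (it is
#'   counted as a non-cropland opinion); a cell that is nodata in *every*
#'   map stays nodata, so unobserved ground is still distinguishable from
#'   unanimous non-cropland.
#' * `"propagate"`: a cell that is nodata in *any* map becomes nodata.
#'
#' @param maps List of at least two aligned [label_grid()]s.
#' @param nodata_policy `"zero-vote"` or `"propagate"` (see Details).
#' @return An object of class `vote_grid`: list with `spec`, `votes`
#'   (integer matrix, `NA` = nodata) and `k_maps`.
#' @export
vote_map <- function(maps, nodata_policy = c("zero-vote", "propagate")) {
  nodata_policy <- match.arg(nodata_policy)
  if (length(maps) < 2L) stop("vote_map needs at least two maps")
  stopifnot(all(vapply(maps, inherits, TRUE, "label_grid")))
  for (g in maps[-1]) stop_if_misaligned(maps[[1]]$spec, g$spec)
  votes <- Reduce(`+`, lapply(maps, function(g) g$labels == 1L))
  nd_count <- Reduce(`+`, lapply(maps, function(g) g$labels == g$nodata_code))
  storage.mode(votes) <- "integer"
  if (nodata_policy == "zero-vote") {
    votes[nd_count == length(maps)] <- NA_integer_
  } else {
    votes[nd_count > 0L] <- NA_integer_
  }
  structure(list(spec = maps[[1]]$spec, votes = votes,
                 k_maps = length(maps)),
            class = "vote_grid")
}

#' @export
print.vote_grid <- function(x, ...) {
  cat(sprintf("vote_grid: %d x %d, K = %d maps, %d nodata cells\n",
              x$spec$n_rows, x$spec$n_cols, x$k_maps, sum(is.na(x$votes))))
  print(table(votes = x$votes[!is.na(x$votes)]))
  invisible(x)
}

#' Threshold a vote grid into a binary consensus map
#'
#' A pixel is cropland when at least `t` maps vote cropland (cumulative
#' reading: `vote >= t`), so threshold 1 is the union of the inputs and
#' threshold K their intersection, and the maps are nested in `t`. Nodata
#' passes through.
#'
#' @param vote A [vote_map()] result.
#' @param t Integer threshold in `1..k_maps`.
#' @param nodata_code Nodata code for the output grid.
#' @return A [label_grid()].
#' @export
threshold_map <- function(vote, t, nodata_code = 255L) {
  stopifnot(inherits(vote, "vote_grid"))
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 1L || t > vote$k_maps)
    stop("threshold t must be a single integer in 1..", vote$k_maps)
  out <- matrix(as.integer(nodata_code), vote$spec$n_rows, vote$spec$n_cols)
  obs <- !is.na(vote$votes)
  out[obs] <- as.integer(vote$votes[obs] >= t)
  label_grid(vote$spec, out, nodata_code = nodata_code)
}

#' Score every consensus threshold against a reference sample and census
#'
#' For each threshold `t = 1..K` the corresponding consensus map is built
#' and scored: the full accuracy metric set against the reference sample
#' (overall, producer's and user's accuracy, omission/commission error, F1,
#' MCC), the mapped cropland area, and the census bias
#' (mapped area minus `census_total`; positive = overestimate).
#'
#' @param vote A [vote_map()] result.
#' @param samples Reference sample data frame with columns `x`, `y`,
#'   `label` (0/1); see [confusion_from_samples()].
#' @param census_total Census cropland area total, in 10^4 ha.
#' @return A data frame of class `sweep_table` with one row per threshold
#'   and columns `threshold, OA, PA, UA, OE, CE, F1, MCC,
#'   mapped_area_1e4ha, census_bias_1e4ha`.
#' @export
threshold_sweep <- function(vote, samples, census_total) {
  stopifnot(inherits(vote, "vote_grid"))
  if (!nrow(samples)) stop("empty reference sample")
  if (census_total < 0) stop("census_total must be non-negative")
  rows <- lapply(seq_len(vote$k_maps), function(t) {
    tm <- threshold_map(vote, t)
    m <- metrics(confusion_from_samples(tm, samples))
    area <- mapped_area(tm)
    data.frame(threshold = t, OA = m$OA, PA = m$PA, UA = m$UA,
               OE = m$OE, CE = m$CE, F1 = m$F1, MCC = m$MCC,
               mapped_area_1e4ha = area,
               census_bias_1e4ha = area - census_total)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Select the consensus threshold from a sweep table
#'
#' Implements the self-adjusted threshold rule: pick the threshold whose map
#' has the highest F1 score, using the smallest absolute census bias to
#' break near-ties. Three formalizations are offered:
#' * `"f1-then-bias"` (default): among rows whose F1 is within
#'   `f1_tie_epsilon` of the maximum, pick the smallest |census bias|. With
#'   `f1_tie_epsilon = 0` this is a pure F1 argmax with bias as tiebreak.
#' * `"f1-max"`: F1 argmax; exact ties broken by smallest |census bias|,
#'   then by smaller threshold.
#' * `"bias-then-f1"`: among rows whose |census bias| is within
#'   `f1_tie_epsilon` (in 10^4 ha) of the minimum, pick the highest F1.
#'
#' @param table A [threshold_sweep()] table (or any data frame with
#'   `threshold`, `F1` and `census_bias_1e4ha` columns).
#' @param rule Selection rule (see Details).
#' @param f1_tie_epsilon Near-tie tolerance; F1 units for the F1-first
#'   rules, 10^4 ha for `"bias-then-f1"`.
#' @return List with `threshold` (the selected integer) and `row` (the
#'   winning table row).
#' @export
select_threshold <- function(table,
                             rule = c("f1-then-bias", "f1-max", "bias-then-f1"),
                             f1_tie_epsilon = 0) {
  rule <- match.arg(rule)
  if (!nrow(table)) stop("empty sweep table")
  stopifnot(all(c("threshold", "F1") %in% names(table)))
  bias <- if ("census_bias_1e4ha" %in% names(table))
    abs(table$census_bias_1e4ha) else rep(NA_real_, nrow(table))
  bias_key <- ifelse(is.na(bias), Inf, bias)
  cand <- switch(rule,
    "f1-max" = which(table$F1 == max(table$F1)),
    "f1-then-bias" = which(table$F1 >= max(table$F1) - f1_tie_epsilon),
    "bias-then-f1" = which(bias_key <= min(bias_key) + f1_tie_epsilon))
  pick <- if (rule == "bias-then-f1") {
    cand[order(-table$F1[cand], table$threshold[cand])][1]
  } else {
    cand[order(bias_key[cand], -table$F1[cand], table$threshold[cand])][1]
  }
  list(threshold = as.integer(table$threshold[pick]), row = table[pick, ])
}

#' Refine a set of cropland maps by the self-adjusted threshold method
#'
#' End-to-end composition: build the vote map, sweep all K thresholds
#' scoring each candidate against the reference sample and census total,
#' select the threshold, and return the corresponding refined cropland map.
#'
#' @inheritParams vote_map
#' @inheritParams threshold_sweep
#' @inheritParams select_threshold
#' @return List with `refined` ([label_grid()]), `sweep`
#'   (the [threshold_sweep()] table), `threshold` (selected integer) and
#'   `vote` (the `vote_grid`).
#' @export
refine <- function(maps, samples, census_total,
                   rule = c("f1-then-bias", "f1-max", "bias-then-f1"),
                   f1_tie_epsilon = 0,
                   nodata_policy = c("zero-vote", "propagate")) {
  rule <- match.arg(rule)
  vote <- vote_map(maps, nodata_policy = match.arg(nodata_policy))
  sweep <- threshold_sweep(vote, samples, census_total)
  sel <- select_threshold(sweep, rule = rule, f1_tie_epsilon = f1_tie_epsilon)
  list(refined = threshold_map(vote, sel$threshold), sweep = sweep,
       threshold = sel$threshold, vote = vote)
}
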