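#' Confusion counts for a binary map
#'
#' Container for the four cells of a binary error matrix. Cropland is the
#' positive class: TP/TN are cropland/non-cropland reference samples mapped
#' correctly, FP is non-cropland mapped as cropland (commission), FN is
#' cropland mapped as non-cropland (omission).
#'
#' @param TP,FP,FN,TN Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  v <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(list(TP = as.numeric(TP), FP = as.numeric(FP),
                 FN = as.numeric(FN), TN = as.numeric(TN)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(map = c("cropland", "non-cropland"),
                              reference = c("cropland", "non-cropland")))
  print(t(m)[2:1, 2:1][2:1, 2:1]) # keep simple 2x2 layout
  invisible(x)
}

#' Tally a confusion matrix from reference points against a map
#'
#' Each sample point is matched to the map pixel containing it (half-open
#' point-in-pixel rule) and its reference label is compared with the map
#' label. Samples outside the grid extent and samples falling on nodata
#' pixels are dropped; the dropped counts are attached as attributes
#' (`dropped_outside`, `dropped_nodata`) and reported via a message so that
#' silent data cleaning is auditable.
#'
#' @param grid A [label_grid()].
#' @param samples Data frame with numeric `x`, `y` and binary `label`
#'   (1 = cropland reference, 0 = non-cropland reference).
#' @param quiet Suppress the dropped-sample message.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_samples <- function(grid, samples, quiet = FALSE) {
  stopifnot(inherits(grid, "label_grid"),
            all(c("x", "y", "label") %in% names(samples)))
  if (!all(samples$label %in% c(0, 1)))
    stop("reference labels must be 0 or 1")
  cell <- point_to_cell(grid$spec, samples$x, samples$y)
  inside <- !is.na(cell$row)
  map_lab <- rep(NA_integer_, nrow(samples))
  map_lab[inside] <- grid$labels[cbind(cell$row[inside], cell$col[inside])]
  usable <- inside & !is.na(map_lab) & map_lab != grid$nodata_code
  n_out <- sum(!inside); n_nd <- sum(inside) - sum(usable)
  if (!quiet && (n_out || n_nd))
    message("confusion_from_samples: dropped ", n_out, " out-of-extent and ",
            n_nd, " nodata-pixel samples")
  if (!sum(usable)) stop("no usable samples (all outside extent or on nodata)")
  ref <- samples$label[usable]; m <- map_lab[usable]
  cm <- confusion_counts(TP = sum(ref == 1 & m == 1L),
                         FP = sum(ref == 0 & m == 1L),
                         FN = sum(ref == 1 & m == 0L),
                         TN = sum(ref == 0 & m == 0L))
  attr(cm, "dropped_outside") <- n_out
  attr(cm, "dropped_nodata") <- n_nd
  cm
}

#' Full-grid confusion of a map against a reference grid
#'
#' Cell-wise error matrix over all cells that are valid (non-nodata) in both
#' grids. Used to score synthetic maps against the known truth.
#'
#' @param map,ref Aligned [label_grid()]s; `ref` supplies the reference
#'   labels.
#' @return A [confusion_counts()] object.
#' @export
confusion_grids <- function(map, ref) {
  stopifnot(inherits(map, "label_grid"), inherits(ref, "label_grid"))
  stop_if_misaligned(map$spec, ref$spec)
  ok <- map$labels != map$nodata_code & ref$labels != ref$nodata_code
  m <- map$labels[ok]; r <- ref$labels[ok]
  confusion_counts(TP = sum(r == 1L & m == 1L), FP = sum(r == 0L & m == 1L),
                   FN = sum(r == 1L & m == 0L), TN = sum(r == 0L & m == 0L))
}

#' Binary classification metrics from a confusion matrix
#'
#' The five standard map-accuracy metrics, with omission/commission error as
#' their complements:
#' \deqn{OA = (TP+TN)/n, \quad PA = TP/(TP+FN), \quad UA = TP/(TP+FP)}
#' \deqn{F1 = 2 \cdot PA \cdot UA / (PA + UA)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' and `OE = 1 - PA`, `CE = 1 - UA`. PA is recall (producer's accuracy), UA
#' precision (user's accuracy); MCC is the Matthews correlation coefficient,
#' robust to the heavy class imbalance typical of cropland validation
#' samples.
#'
#' Degenerate conventions (so threshold sweeps stay total at the extremes):
#' PA and UA are 0 when their denominator is 0, F1 is 0 when PA + UA = 0,
#' and MCC is 0 when any marginal of the matrix is 0.
#'
#' @param cm A [confusion_counts()] object.
#' @return An object of class `metric_set`: list with `OA`, `PA`, `UA`,
#'   `OE`, `CE`, `F1`, `MCC`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  TP <- cm$TP; FP <- cm$FP; FN <- cm$FN; TN <- cm$TN
  n <- TP + FP + FN + TN
  if (n == 0) stop("all-zero confusion matrix")
  OA <- (TP + TN) / n
  PA <- if (TP + FN > 0) TP / (TP + FN) else 0
  UA <- if (TP + FP > 0) TP / (TP + FP) else 0
  F1 <- if (PA + UA > 0) 2 * PA * UA / (PA + UA) else 0
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else 0
  structure(list(OA = OA, PA = PA, UA = UA, OE = 1 - PA, CE = 1 - UA,
                 F1 = F1, MCC = MCC),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  v <- round(unlist(x), digits)
  print(v)
  invisible(x)
}

#' Build a stratified accuracy-assessment design from a map and samples
#'
#' Assembles the inputs for design-based (stratified) accuracy and area
#' estimation: stratum membership and reference-label counts for every
#' sample, plus each stratum's area weight `W_i` (its share of the valid map
#' cells). By default the strata are the assessed map's own classes — the
#' standard design for map accuracy assessment — but any integer stratum
#' raster (e.g. the vote map used to allocate a stratified sample) can be
#' supplied.
#'
#' @param map A [label_grid()] whose accuracy/area is being estimated.
#' @param samples Labeled reference sample (`x`, `y`, `label`).
#' @param strata Optional stratum raster: a `vote_grid` or a [label_grid()]
#'   aligned with `map`; default `NULL` uses the map's own classes.
#' @return An object of class `stratified_design`: data frame with one row
#'   per (stratum, map class) cell containing `stratum`, `map_class`, `W`
#'   (stratum area weight, repeated within stratum), `n_ref0`, `n_ref1`.
#' @export
accuracy_design <- function(map, samples, strata = NULL) {
  stopifnot(inherits(map, "label_grid"))
  strat_vals <- if (is.null(strata)) {
    m <- map$labels; m[m == map$nodata_code] <- NA_integer_; m
  } else if (inherits(strata, "vote_grid")) {
    stop_if_misaligned(map$spec, strata$spec)
    strata$votes
  } else if (inherits(strata, "label_grid")) {
    stop_if_misaligned(map$spec, strata$spec)
    m <- strata$labels; m[m == strata$nodata_code] <- NA_integer_; m
  } else stop("strata must be NULL, a vote_grid or a label_grid")

  cell <- point_to_cell(map$spec, samples$x, samples$y)
  inside <- !is.na(cell$row)
  idx <- cbind(cell$row[inside], cell$col[inside])
  s_map <- map$labels[idx]
  s_str <- strat_vals[idx]
  ref <- samples$label[inside]
  usable <- s_map != map$nodata_code & !is.na(s_str)
  s_map <- s_map[usable]; s_str <- s_str[usable]; ref <- ref[usable]
  if (!length(ref)) stop("no usable samples for the design")

  valid <- !is.na(strat_vals) & map$labels != map$nodata_code
  sizes <- table(strat_vals[valid])
  W <- as.numeric(sizes) / sum(sizes)
  names(W) <- names(sizes)

  key <- interaction(s_str, s_map, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    data.frame(stratum = s_str[sel][1], map_class = s_map[sel][1],
               n_ref0 = sum(ref[sel] == 0), n_ref1 = sum(ref[sel] == 1))
  })
  out <- do.call(rbind, rows)
  out$W <- W[as.character(out$stratum)]
  out <- out[order(out$stratum, out$map_class),
             c("stratum", "map_class", "W", "n_ref0", "n_ref1")]
  rownames(out) <- NULL
  # strata with no samples cannot contribute; their weight must be present
  if (anyNA(out$W)) stop("sampled stratum missing from the stratum raster")
  class(out) <- c("stratified_design", "data.frame")
  out
}

#' Design-based (stratified) accuracy and area estimates
#'
#' Re-weights the sample error matrix by the stratum area proportions
#' `W_i` to obtain approximately unbiased accuracy and area estimates with
#' standard errors, following the good-practice stratified estimators for
#' map accuracy assessment. Cell proportions are
#' `p_hat[m, j] = sum_i W_i * n_i(m, j) / n_i` (map class m, reference class
#' j, stratum i); the cropland area proportion is `p_hat[., 1]`, its
#' standard error
#' \deqn{SE(\hat p_{\cdot j}) = \sqrt{\sum_i W_i^2
#'   \frac{(n_{ij}/n_i)(1 - n_{ij}/n_i)}{n_i - 1}}}
#' and the area estimate is `p_hat * total_area` with a normal 95% CI.
#'
#' Adjusted OA/UA/PA are computed from the cell proportions. Their standard
#' errors are reported for the standard design where strata coincide with
#' the map classes; for other stratifications the accuracy SEs are `NA`
#' (the area estimates and their SEs are valid for any stratification).
#'
#' @param design A [accuracy_design()] data frame (or one assembled by
#'   hand with columns `stratum`, `map_class`, `W`, `n_ref0`, `n_ref1`).
#' @param total_area Total valid map area in 10^4 ha (e.g.
#'   `mapped_area()` of an all-ones grid, or the known region area).
#' @return An object of class `adjusted_estimate`: list with `OA`, `OA_se`,
#'   per-class `UA`, `PA` and their SEs, `p_area` (reference-class area
#'   proportions, sums to 1), `p_area_se`, `area_1e4ha`, `area_se_1e4ha`,
#'   `ci_lower_1e4ha`, `ci_upper_1e4ha` (95%), and `n` (samples used).
#' @export
adjusted_estimates <- function(design, total_area) {
  stopifnot(is.data.frame(design),
            all(c("stratum", "map_class", "W", "n_ref0", "n_ref1")
                %in% names(design)))
  agg <- stats::aggregate(cbind(n_ref0, n_ref1) ~ stratum, data = design, sum)
  agg$n <- agg$n_ref0 + agg$n_ref1
  Wtab <- design[!duplicated(design$stratum), c("stratum", "W")]
  agg <- merge(agg, Wtab, by = "stratum")
  if (abs(sum(agg$W) - 1) > 1e-9) stop("stratum weights must sum to 1")
  if (any(agg$n < 2)) stop("every stratum needs n_i >= 2 for SE computation")
  n_i <- stats::setNames(agg$n, agg$stratum)
  W_i <- stats::setNames(agg$W, agg$stratum)

  # area proportions of reference classes (any stratification)
  pij <- function(j) {
    nij <- stats::setNames(agg[[paste0("n_ref", j)]], agg$stratum)
    sum(W_i * nij / n_i)
  }
  seij <- function(j) {
    nij <- stats::setNames(agg[[paste0("n_ref", j)]], agg$stratum)
    q <- nij / n_i
    sqrt(sum(W_i^2 * q * (1 - q) / (n_i - 1)))
  }
  p_area <- c(`0` = pij(0), `1` = pij(1))
  p_se <- c(`0` = seij(0), `1` = seij(1))

  # cell proportions p_hat[m, j]
  dW <- W_i[as.character(design$stratum)]
  dn <- n_i[as.character(design$stratum)]
  phat <- matrix(0, 2, 2, dimnames = list(map = c("0", "1"),
                                          ref = c("0", "1")))
  for (r in seq_len(nrow(design))) {
    m <- as.character(design$map_class[r])
    phat[m, "0"] <- phat[m, "0"] + dW[r] * design$n_ref0[r] / dn[r]
    phat[m, "1"] <- phat[m, "1"] + dW[r] * design$n_ref1[r] / dn[r]
  }
  OA <- phat["0", "0"] + phat["1", "1"]
  UA <- c(`0` = phat["0", "0"] / sum(phat["0", ]),
          `1` = phat["1", "1"] / sum(phat["1", ]))
  PA <- c(`0` = phat["0", "0"] / sum(phat[, "0"]),
          `1` = phat["1", "1"] / sum(phat[, "1"]))

  # SEs for the map-class-strata design (the standard case)
  strata_are_classes <- nrow(agg) == nrow(design) &&
    all(design$stratum == design$map_class) &&
    setequal(design$map_class, c(0, 1))
  OA_se <- UA_se <- PA_se <- NULL
  if (strata_are_classes) {
    d <- design[match(c(0, 1), design$stratum), ]
    ncorr <- ifelse(d$map_class == 0, d$n_ref0, d$n_ref1)
    ua <- ncorr / (d$n_ref0 + d$n_ref1)
    nn <- d$n_ref0 + d$n_ref1
    OA_se <- sqrt(sum(d$W^2 * ua * (1 - ua) / (nn - 1)))
    UA_se <- stats::setNames(sqrt(ua * (1 - ua) / (nn - 1)), c("0", "1"))
    PA_se <- vapply(c(0, 1), function(j) {
      jj <- as.character(j); oth <- as.character(1 - j)
      Nj_hat <- sum(phat[, jj])                  # est. proportion of ref class j
      paj <- PA[[jj]]; uaj <- ua[d$map_class == j]
      njn <- nn[d$map_class == j]; Wj <- d$W[d$map_class == j]
      Wo <- d$W[d$map_class == (1 - j)]; no <- nn[d$map_class == (1 - j)]
      qo <- (if (j == 0) d$n_ref0 else d$n_ref1)[d$map_class == (1 - j)] / no
      sqrt((Wj^2 * (1 - paj)^2 * uaj * (1 - uaj) / (njn - 1) +
              paj^2 * Wo^2 * qo * (1 - qo) / (no - 1)) / Nj_hat^2)
    }, 0)
    names(PA_se) <- c("0", "1")
  }

  area <- p_area * total_area
  se_area <- p_se * total_area
  structure(list(OA = OA, OA_se = OA_se, UA = UA, UA_se = UA_se,
                 PA = PA, PA_se = PA_se,
                 p_area = p_area, p_area_se = p_se,
                 area_1e4ha = area, area_se_1e4ha = se_area,
                 ci_lower_1e4ha = area - 1.96 * se_area,
                 ci_upper_1e4ha = area + 1.96 * se_area,
                 n = sum(agg$n)),
            class = "adjusted_estimate")
}

#' @export
print.adjusted_estimate <- function(x, ...) {
  cat(sprintf("adjusted OA: %.4f%s\n", x$OA,
              if (!is.null(x$OA_se)) sprintf(" (SE %.4f)", x$OA_se) else ""))
  cat(sprintf("cropland area: %.2f [%.2f, %.2f] x10^4 ha (n = %d)\n",
              x$area_1e4ha[["1"]], x$ci_lower_1e4ha[["1"]],
              x$ci_upper_1e4ha[["1"]], x$n))
  invisible(x)
}

#' Accuracy metrics per zone
#'
#' Partitions the reference samples by the zone raster and computes the full
#' metric set per zone (e.g. per province). Zones with no usable samples are
#' kept in the output and flagged rather than dropped.
#'
#' @param grid A [label_grid()].
#' @param samples Labeled reference sample (`x`, `y`, `label`).
#' @param zones A [zone_grid()] aligned with `grid`.
#' @return Data frame with one row per zone id: sample count, confusion
#'   counts, metrics, and `no_samples` flag.
#' @export
per_zone_metrics <- function(grid, samples, zones) {
  stopifnot(inherits(grid, "label_grid"), inherits(zones, "zone_grid"))
  stop_if_misaligned(grid$spec, zones$spec)
  cell <- point_to_cell(zones$spec, samples$x, samples$y)
  inside <- !is.na(cell$row)
  zid <- rep(NA_integer_, nrow(samples))
  zid[inside] <- zones$zones[cbind(cell$row[inside], cell$col[inside])]
  all_zones <- sort(unique(as.vector(zones$zones)))
  all_zones <- all_zones[!is.na(all_zones)]
  rows <- lapply(all_zones, function(z) {
    sub <- samples[!is.na(zid) & zid == z, , drop = FALSE]
    base <- data.frame(zone = z, n = nrow(sub), TP = NA_real_, FP = NA_real_,
                       FN = NA_real_, TN = NA_real_, OA = NA_real_,
                       PA = NA_real_, UA = NA_real_, OE = NA_real_,
                       CE = NA_real_, F1 = NA_real_, MCC = NA_real_,
                       no_samples = TRUE)
    if (!nrow(sub)) return(base)
    cm <- tryCatch(confusion_from_samples(grid, sub, quiet = TRUE),
                   error = function(e) NULL)
    if (is.null(cm)) return(base)
    m <- metrics(cm)
    data.frame(zone = z, n = nrow(sub), TP = cm$TP, FP = cm$FP, FN = cm$FN,
               TN = cm$TN, OA = m$OA, PA = m$PA, UA = m$UA, OE = m$OE,
               CE = m$CE, F1 = m$F1, MCC = m$MCC, no_samples = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract commission/omission-flagged error samples
#'
#' Returns the misclassified reference points, each tagged `"commission"`
#' (non-cropland reference mapped as cropland, FP) or `"omission"` (cropland
#' reference mapped as non-cropland, FN), for spatial error inspection and
#' export.
#'
#' @inheritParams confusion_from_samples
#' @return The subset of `samples` that is misclassified, with an added
#'   `error` column.
#' @export
error_samples <- function(grid, samples, quiet = TRUE) {
  stopifnot(inherits(grid, "label_grid"))
  cell <- point_to_cell(grid$spec, samples$x, samples$y)
  inside <- !is.na(cell$row)
  map_lab <- rep(NA_integer_, nrow(samples))
  map_lab[inside] <- grid$labels[cbind(cell$row[inside], cell$col[inside])]
  usable <- inside & !is.na(map_lab) & map_lab != grid$nodata_code
  flag <- rep(NA_character_, nrow(samples))
  flag[usable & samples$label == 0 & map_lab == 1L] <- "commission"
  flag[usable & samples$label == 1 & map_lab == 0L] <- "omission"
  out <- samples[!is.na(flag), , drop = FALSE]
  out$error <- flag[!is.na(flag)]
  rownames(out) <- NULL
  out
}
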