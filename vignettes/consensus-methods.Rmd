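---
title: "Consensus refinement and design-based validation of binary cropland maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus refinement and design-based validation of binary cropland maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropconsensus)
```

## The problem

Contemporary remotely sensed land-cover products disagree substantially about
where cropland is, especially in regions with fragmented parcels, complex
topography and few clear-sky observations. Given K co-registered binary
cropland maps, an independent reference sample, and census areas for
administrative zones, `cropconsensus` builds a per-pixel *vote map* (how many
products call a pixel cropland), scores every consensus threshold
t = 1..K, and selects a refined map by the rule *highest F1, lowest absolute
census bias*. Around that core it provides design-based (stratified) accuracy
and area estimation, multi-source sample pooling, stratified sampling on vote
strata, and census agreement statistics.

## The model and its assumptions

**Harmonization.** All grids must share one analysis grid: same origin, pixel
size, dimensions and CRS tag. The CRS is assumed *equal-area*, so cropland
area is (cropland-pixel count) x (pixel area); areas are reported in
10^4 ha (one 30 m pixel is 0.09 ha). The package performs no reprojection —
products arrive co-registered (nearest-neighbour resampling onto the target
grid is provided for grids that share the CRS but not the resolution).
Pixels are half-open cells `[edge, edge + size)`, row 1 northernmost, and a
point (x, y) belongs to exactly one pixel; reference points are matched to
map labels by this rule.

**Voting and thresholding.** The vote map counts cropland votes per pixel.
Thresholding is cumulative (`vote >= t`), which makes the candidate maps
nested: threshold 1 is the union of the products, threshold K their
intersection, and mapped area is non-increasing in t. With a fixed reference
sample, nestedness also forces producer's accuracy to be non-increasing in t
while user's accuracy typically rises — the sweep traces the
omission/commission trade-off, and F1 peaks at an interior threshold whenever
the products err roughly independently.

**Scoring.** Each candidate is scored with the standard binary map-accuracy
metrics — overall accuracy, producer's accuracy (recall), user's accuracy
(precision), F1, and the Matthews correlation coefficient, which remains
informative under the heavy class imbalance typical of cropland reference
sets — plus the mapped area and its bias against the census total
(mapped − census; positive = overestimate).

**Selection.** The dual "highest F1 / lowest bias" principle is not a total
order, so three formalizations are exposed. The default, `f1-then-bias` with
`f1_tie_epsilon = 0`, is a pure F1 argmax with absolute census bias as
tiebreak; a positive epsilon lets near-max-F1 candidates compete on bias, and
`bias-then-f1` is the symmetric reading. The default reproduces the
maximum-F1 choice on any sweep with a unique F1 maximum.

**Design-based estimation.** Sample-based metrics estimate map accuracy only
under the sample's design. `adjusted_estimates()` implements the
good-practice stratified estimators: with stratum area weights W_i and
per-stratum reference counts n_ij, cell proportions are
p(m, j) = sum_i W_i n_i(m, j)/n_i; adjusted OA/UA/PA follow from the
proportion matrix, the cropland area proportion is p(., 1) with the standard
stratified variance estimator, and areas get normal 95% CIs. Accuracy
standard errors are reported for the standard design whose strata are the
assessed map's own classes; area estimates and their SEs are valid for any
stratification (including vote-map strata). The estimators assume simple
random sampling within strata and a negligible sampling fraction (no finite
population correction).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nodata_policy` | `zero-vote` | a product's nodata pixel casts no vote; a pixel unobserved by *all* products stays nodata. `propagate` blanks any pixel with at least one nodata vote. |
| `rule`, `f1_tie_epsilon` | `f1-then-bias`, 0 | threshold selection (above); epsilon in F1 units |
| `dedup_tolerance` | half a pixel (15 m at 30 m) | merge distance for multi-source pools; earlier pools have priority |
| `min_per_stratum` | 0 | floor on stratified-sample quotas after largest-remainder allocation |
| `tie` (temporal majority) | `cropland` | label when 0/1 occur equally often in a stack; favouring detection mirrors the convention of flagging cropland if a growing crop was ever detected |
| `nodata_code` | 255 | reserved uint8 code in files and grids |

## The synthetic scene generator

`generate_scene()` builds complete test worlds: a spatially autocorrelated
binary truth (seeded uniform noise, repeated box smoothing at the stated
correlation length, rank-thresholded to hit the cropland fraction exactly to
one cell), K products corrupted by per-map omission/commission rates
(independent flips, or patchy flips driven by a thresholded correlated field
with the same marginal rates), a rectangular-block zone partition with a
coarser province grouping, and a census equal to the truth's zonal areas
(optionally with seeded multiplicative noise). One master seed spawns
per-component substreams, so scenes are byte-reproducible and components can
be varied independently.

Defaults — 512 x 512 pixels at 30 m, cropland fraction 0.3, truth correlation
length 8 pixels, K = 10 products at omission 0.2 / commission 0.1 with
independent errors, 9 zones, exact census — describe a fragmented smallholder
landscape observed by ten imperfect products and are the reference conditions
for the end-to-end tests. The unit and property tests run reduced grids
(64–256 pixels a side) where the property under test does not need the full
scene.

What the generator does *not* emulate: terrain- or class-dependent error
geography beyond a single correlation length, product errors correlated
*across* products (shared training data make real products err together,
which weakens consensus gains), geolocation error, mixed pixels, and
reference-label noise. Passing tests therefore demonstrate the machinery and
its statistical calibration under stated error models, not the accuracy of
any real product.

## Numerical choices and degenerate inputs

* Metric conventions at degenerate matrices: PA or UA is 0 when its
  denominator is 0, F1 is 0 when PA + UA = 0, MCC is 0 when any marginal is
  0. This keeps full sweeps well-defined at extreme thresholds.
* Largest-remainder rounding turns real allocations into integer quotas that
  sum exactly to the requested n; quotas below `min_per_stratum` are raised
  and the excess is taken back from the largest quotas.
* Sample points are placed at pixel centers, making label lookup exact and
  draws reproducible; within-stratum sampling is without replacement.
* Stratum weights must sum to 1 within 1e-9; every stratum needs n_i >= 2
  for variance estimation.
* GeoTIFF I/O is a deliberately minimal codec (uncompressed baseline TIFF,
  single band, 8/16/32-bit integers, north-up geotransform via
  pixel-scale/tiepoint tags, `GDAL_NODATA`); rotated/sheared rasters are
  rejected rather than resampled, and the CRS tag string rides in
  `ImageDescription`. Files are cross-checked against an independent TIFF
  implementation in the test suite.

## Open design choices

* **Threshold semantics** are cumulative (`vote >= t`); the alternative
  equality reading would not produce monotonically shrinking areas and
  contradicts nested threshold maps.
* **Strata for sampling** are the distinct vote values (the finest faithful
  reading of strata defined by the consistency map); custom binning is
  possible via `allocation = "custom"`.
* **Census bias sign** is mapped − census, so positive means the map
  overestimates cropland.
* **Agreement R²** is implemented literally as
  1 − Σ(x−y)²/Σ(y−ȳ)² — a skill score against the 1:1 line that can go
  negative — because axis labels on published scatter plots are ambiguous
  between this and squared Pearson correlation; `compare_table()` reports
  both, clearly named.
* **Zone exclusions** (administrative units whose level does not match) are
  configuration, not code.

## Known limitations

* Binary classes only; no multi-class error matrices or fuzzy agreement.
* No reprojection; equal-area semantics are asserted via the CRS tag, not
  verified.
* The uint8 writer caps zone rasters at 254 zones (readers accept wider
  integer types).
* Accuracy SEs are only emitted for map-class strata; for other designs the
  point estimates are still valid but interval estimates cover areas only.

## Reproducing the end-to-end behaviour

```{r example, eval = FALSE}
p <- scene_params(seed = 1)          # the reference study conditions
sc <- generate_scene(p)
v <- vote_map(sc$products)
pts <- label_from_truth(
  stratified_sample(v, 1500, restrict_to_extent = FALSE,
                    min_per_stratum = 2, seed = 2), sc$truth)
res <- refine(sc$products, pts, sum(sc$census$area_1e4ha))
res$sweep
res$threshold
```

`parameter_recovery_suite()` repeats this over seeds and aggregates refined
vs single-product F1, interior-threshold frequency and the coverage of the
design-based area CI; the test suite runs it at the default conditions over
20 seeds.
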