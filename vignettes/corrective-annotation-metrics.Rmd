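---
title: "Corrective-annotation metrics, region measurement and scale calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrective-annotation metrics, region measurement and scale calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrseg)
```

## The problem

Interactive ("human-in-the-loop") segmentation tools train a model while the
user corrects its predictions: on each training image the user paints green
over pixels the model wrongly claimed as foreground (false positives) and red
over foreground pixels it missed (false negatives). Those corrective strokes
do double duty. They are the next round of training data, and — under the
working assumption that a fully corrected segmentation is accurate — they
implicitly define a ground truth against which the *current* prediction can
be scored. That turns every annotated image into a free evaluation point and
makes it possible to decide, objectively, when a model has stopped improving
and training can end.

`corrseg` implements the full measurement stack around such a workflow for
benthic (seafloor) imagery: per-image corrective metrics and a rolling-mean
stopping rule, connected-component region measurement, pixel-to-centimetre
calibration from paired ROV laser dots or a fixed reference length, and
dataset-level validation statistics. A seeded synthetic-scene generator with
exact bookkeeping makes every stage testable without any image download.

## Corrective metrics

For a prediction $P$ and corrections $(G, R)$ the corrected segmentation is
$C = (P \setminus G) \cup R$. Treating $C$ as truth gives the confusion
counts

$$\mathrm{FP} = |G \cap P|, \quad \mathrm{FN} = |R \setminus P|, \quad
\mathrm{TP} = |P| - \mathrm{FP},$$

from which the per-image metrics follow:
precision $\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$,
recall $\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$,
dice $2\,\mathrm{TP}/(2\,\mathrm{TP}+\mathrm{FP}+\mathrm{FN})$ (the harmonic
mean of precision and recall), accuracy
$(\mathrm{TP}+\mathrm{TN})/N$, and the signed area error
$|P| - |C| = |G \cap P| - |R \setminus P|$, whose positive sign means
over-prediction.

Three conventions are deliberate:

* **Empty/empty images score 1.** When an image contains no true foreground
  and the model predicts none, all ratio metrics are taken as 1 rather than
  undefined or 0. Foreground-sparse frames are common in survey footage, and
  ratio metrics already reflect disproportionately harshly on performance
  when foreground pixels are few; penalising a correct "nothing here" would
  make the training log useless on sparse sequences.
* **Redundant strokes are ignored, with a count.** Green outside the
  prediction and red inside it are no-ops (the set algebra makes them so);
  they are tallied on the corrected mask (`redundant_green`,
  `redundant_red`) because a rising count usually means the annotator is
  correcting a stale prediction, but they are not errors. Real corrective
  strokes are sloppy, and a workflow that hard-errors on them is unusable.
* **Incomplete correction is surfaced, not repaired.** If the user corrects
  only part of the errors, corrective metrics can only flatter the model
  (every uncorrected error pixel is silently counted as correct). Each
  training-log record therefore carries `annotated_fraction` as a
  diagnostic; no attempt is made to extrapolate the un-annotated errors.

## The stopping rule

`stopping_rule()` encodes the quantitative criterion: training ends when the
trailing rolling mean (default window $n = 10$) of the per-image dice score
reaches a threshold (default 0.95). The rolling statistic is a plain
unweighted trailing mean; the value reported at index $i$ averages records
$i-n+1 \dots i$ and nothing is reported before the first full window.

One boundary case needs a decision. With a window of ten, nine perfect
images and one at dice 0.5 average *exactly* 0.95. We treat that window as
still containing the transition and only fire once the mean strictly
exceeds the threshold — on the constructed sequence (ten images at 0.5,
then perfect) the rule fires at 0-based index 19, the first window that has
fully cleared the bad stretch. `stopping_index(..., inclusive = TRUE)`
restores the tie-inclusive reading, which is required if you set the
threshold to 1 (a mean can never exceed 1). Thresholds must lie in $(0, 1]$.

```{r}
log <- tibble::tibble(index = 0:29, dice = c(rep(0.5, 10), rep(1, 20)))
stopping_index(log, stopping_rule(window_n = 10, threshold = 0.95))
```

## Region measurement

`label_components()` labels foreground components with a run-merging
union-find pass; labels are assigned in row-major first-pixel order so the
labelling is reproducible. The default 8-connectivity counts diagonally
adjoining lobes as one individual — the convention used when delimiting
lobed sponges in survey imagery — and 4-connectivity is available where
stricter separation is wanted.

`region_properties()` reports, per region:

* **area** — the pixel count;
* **centroid** — the mean pixel coordinate, sub-pixel, exported 0-based with
  `x` = column and `y` = row (image convention, origin top-left);
* **equivalent diameter** — $2\sqrt{A/\pi}$, the diameter of the circle with
  the region's area ("diameter" of an irregular blob is otherwise
  ill-defined);
* **eccentricity** — from the ellipse sharing the region's second central
  moments: with covariance eigenvalues $\lambda_1 \ge \lambda_2$,
  $e = \sqrt{1 - \lambda_2/\lambda_1}$, 0 for a circle, approaching 1 for a
  line. Single pixels get 0 by convention; 1-pixel-wide lines have
  $\lambda_2 = 0$ and are capped just below 1 so the value stays in
  $[0, 1)$;
* **perimeter** — a chain-code walk of the region's outer contour
  (Moore tracing). The naive step weights (1 orthogonal, $\sqrt 2$
  diagonal) carry a well-known digitization bias: on rasterized disks the
  walk over-measures $2\pi r$ by a stable 5.0–5.5 % regardless of radius.
  We therefore use the classical Vossepoel–Smeulders corrected weights
  (0.980 per orthogonal step, 1.406 per diagonal step, −0.091 per direction
  change), which brought the worst disk error across radii 20–61 px down to
  2.4 % in our checks; raw chain length is available via
  `perimeter_weights = "chain"`. Interior holes are not traced, and a
  single pixel has perimeter 0.

Because the moments are ratios, eccentricity is scale- and
rotation-invariant up to rasterization noise; the tests pin this at 0.02
absolute tolerance against analytic ellipses.

## Scale calibration

ROV footage has no fixed image scale — the camera moves — so each frame is
calibrated independently from two parallel lasers projected 5 cm apart. From
a segmented laser mask, regions smaller than `min_region_px` (default 3 px)
are discarded as noise; if exactly two regions survive, the Euclidean
distance between their sub-pixel centroids divided by the true separation
gives px/cm. Any other count excludes the frame: one dot usually means a
laser fell outside the frame, three or more usually means reflections. The
excluded frame keeps its pixel measurements and carries an exclusion status
rather than raising an error, preserving the audit trail. Centroids, not
brightest pixels, localise the dots: they are robust to dot size and need
no intensity information.

Fixed-camera datasets instead use a reference structure of known size; the
default is a cold-water coral branch width of 0.43 cm (spread ±0.09 cm,
carried as a relative error on the scale factor, not as a distribution).
Areas — and signed area errors, identically — convert by
$(1/\text{px-per-cm})^2$, and `relative_areas()` normalises a series by its
maximum for cross-dataset comparison of contraction cycles.

## Dataset-level validation

`pooled_metrics()` micro-averages: confusion counts are summed over all
images and the formulas applied once. Pooling weights pixels, not images —
a property the tests pin with a two-image counterexample where the naive
mean of per-image precisions (0.5) differs from the pooled value (0.9).

`area_difference_summary()` reports the mean absolute difference of scaled
areas with sample (n−1) standard deviations, plus the percentage difference
relative to the manual area. "Average difference" is ambiguous in common
usage, so the signed mean (predicted − manual) is always reported alongside
the absolute one. `area_agreement()` regresses predicted on corrected/true
areas by OLS; its intercept is the natural reading of a "consistently
over-predicts by X cm²" statement, and the model-free mean signed error is
reported next to it since that phrasing does not disambiguate the two.
`classify_success()` applies the published working thresholds (precision
≥ 0.71, recall ≥ 0.75, dice ≥ 0.74, accuracy ≥ 0.76), inclusively.

## The synthetic generator

The generator emulates the structural features the measurement stack
actually consumes:

* **Scenes** — lobed blobs (unions of overlapping ellipses) on a textured
  background, placed by rejection sampling so they never touch the border
  or each other (the texture is cosmetic; no computation reads it).
* **Predictions** — the truth corrupted by a signed morphological boundary
  change, whole-blob deletions, and false-positive speckles, with the exact
  confusion counts returned as bookkeeping.
* **Corrections** — each error pixel marked independently with probability
  `completeness`; 1 reproduces the truth exactly, lower values emulate
  partial correction. No spatial stroke model is attempted.
* **Trajectories** — corruption magnitudes decaying as
  $\exp(-i/\tau)$, emulating training improvement; per-frame seeds derive
  from one master seed, so sequences are bit-reproducible.
* **Laser frames** — two rasterized dots at a known centroid separation
  (within half a pixel of rasterization error) at a random near-horizontal
  orientation.

What the generator does *not* emulate is as important: turbidity and
lighting changes, occlusion by mobile fauna, camera malfunctions,
perspective distortion of scale across a frame, and correlated,
stroke-shaped annotation noise. Tests passing on synthetic scenes therefore
establish the correctness of the arithmetic and the geometry, not
field-readiness of any particular segmentation model.

Two numerical choices in the corruption model deserve a note. The
morphological disc of radius $r$ uses the offset set
$\{d : \|d\|^2 \le (r+0.5)^2\}$ — the standard discrete approximation of a
Euclidean disc; the plain $r^2$ cut-off under-reaches on diagonals and
biases dilation/erosion ring areas low by about 10 %, which would defeat
ring-area checks. Blob placement retries at most 1000 times and then fails
("infeasible packing"): deterministic failure is preferred to silent
overlap, which would break the region-count bookkeeping.

## Problem sizes and runtime

The test-suite and acceptance-script simulations use 96×96-pixel scenes
with two blobs of 7–13 px semi-axes, 60-image trajectories with
$\tau = 8$, 100-scene property sweeps, and $n = 400$ agreement simulations
over 50 seeds — sizes at which every property under test (rasterization
tolerances, binomial expectations, OLS coverage) is already stable while
the full suite runs in well under a minute. The agreement simulation draws
true areas from a lognormal distribution (sdlog = 1): a heavy-tailed size
spread is realistic for benthic individuals and makes the OLS intercept
standard error close to $\sigma/\sqrt n$, so intercept-recovery coverage
can be stated against that simple yardstick.

## Known limitations

* Perimeter ignores interior holes (outer contour only); for the lobed,
  mostly convex shapes this stack measures, holes are rare and small.
* Corrective metrics are computed over all pixels of the image, following
  the assumption that a corrected segmentation is accurate everywhere — if
  an annotator only inspects part of the frame, the metrics inherit that
  blind spot (watch `annotated_fraction`).
* Laser calibration applies one scale factor per frame; terrain slope and
  perspective make the true scale vary within a frame, and nothing here
  corrects for that.
* Anomaly flagging (`flag_anomalies()`) is a conservative heuristic proxy
  for a human sweep through segmentation thumbnails; its thresholds are
  advisory and every flagged frame stays in the row-level output.
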