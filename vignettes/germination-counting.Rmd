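---
title: "Counting Striga seed germination in filter-assay images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting Striga seed germination in filter-assay images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germVision)
```

## The problem

*Striga hermonthica* is an obligate root-parasitic weed of cereals whose
seed bank drives infestation across Sub-Saharan Africa and Southeast Asia.
Screens for germination stimulants (suicidal-germination agents such as the
strigolactone analogue GR24) or suppressants are run as glass-fibre filter
assays: roughly 50 seeds on a 13 mm filter disc are exposed to a treatment
and scored under a dissecting microscope. The seeds are under 200 µm
across, so scoring is slow and error-prone, and the readout per filter is
three numbers: total seeds, radicle onsets (each visible embryonic root
marks one germinated seed), and the germination percentage

$$
\mathrm{germination\ \%} \;=\; 100 \cdot \frac{n_{\mathrm{radicle}}}{n_{\mathrm{seed}}}.
$$

germVision implements an automated counting workflow around this readout:
annotation handling, detection post-processing, per-image counting, and the
model-selection machinery that picks a detector operating point by how well
it reproduces hand-counted germination percentages — together with a
synthetic assay simulator so every stage is testable without real imagery
or trained network weights.

## The detection model and its post-processing

The workflow is built around single-shot grid-and-anchor object detection
with two classes, `seed` and `radicle` (plus `haustorium` reserved for an
extended three-class system). A detector of this family divides its square
input (resolution 608) into an $S \times S$ grid; each cell carries $A = 3$
anchor boxes — prior shapes derived from the training annotations — and
emits per anchor four box parameters $(t_x, t_y, t_w, t_h)$, an objectness
logit, and class logits. `decodeRaw()` applies the standard
parameterization,

$$
(c_x, c_y) = \big(j + \sigma(t_x),\, i + \sigma(t_y)\big)\cdot\frac{608}{S},
\qquad
(w, h) = (w_a e^{t_w},\, h_a e^{t_h}),
$$

yielding exactly $S^2 A$ candidate detections. Downstream, two operations
shape the counts:

* `objectnessFilter(dets, P)` keeps detections with objectness $\ge P$
  (the inclusive rule is this package's choice; the convention only states
  that detections *below* the threshold are discarded). Objectness alone is
  the confidence used — not objectness times class probability.
* `nms(dets, 0.45)` performs greedy class-wise non-maximum suppression.
  Suppression is deliberately class-wise because a radicle-onset box
  legitimately overlaps its seed's box; the 0.45 default is the common
  detector convention. The source workflow does not describe suppression —
  a decoder without it would multi-count — so it is added here explicitly
  and tested against exhaustive subset search.

Anchors come from `kmeansAnchors()`: K-means (default $K = 9$) over the
annotated box shapes under the $1 - \mathrm{IoU}$ distance between
center-aligned boxes, the convention introduced with anchor clustering;
plain Euclidean clustering of $(w,h)$ is available as an option and
delegates to `stats::kmeans`. Because a mean-shape update does not in
general guarantee descent of the $1-\mathrm{IoU}$ objective, the iteration
records the objective each pass and stops — keeping the previous
representatives — if an update would increase it; empty clusters are
reseeded with the worst-fitting box. The exact distance used by the
original training pipeline is unstated; the IoU form is the default here
because it is the one anchor clustering was designed around.

The training recipe of the reference detector (SGD, momentum 0.9, learning
rate $10^{-3}$, weight decay $5\times 10^{-4}$, 20 000 epochs with tenfold
learning-rate drops at 16 000 and 18 000, input resolution 608, HSV/flip/
jitter augmentation) is carried as serializable metadata
(`trainingRecipe()`); executing training is out of scope, so the recipe is
a record, not a runnable.

## Model selection by germination difference

The selection metric is the **average germination difference**: the mean
over images of $|\hat{g} - g|$ in percentage points, where $\hat{g}$ and
$g$ are predicted and hand-counted germination percentages. It is a
per-image mean of absolute differences, not a pooled-count difference.
Images with undefined germination (zero seeds on either side) are excluded
and tallied, a case the source data never hit — the behaviour is this
package's choice.

`sweepThreshold()` re-applies filter + NMS + counting at each $P$ on a grid
(default $0.01$–$0.10$ in steps of $0.01$) and selects the minimizing $P$;
`sweepCheckpoints()` does the same across checkpoints at fixed $P = 0.05$.
Ties break toward the smaller threshold / earlier checkpoint, since the
reference workflow reports unique minima and states no rule. Per-class bias
is reported as signed underestimation,
$(\mathrm{hand} - \mathrm{tool})/\mathrm{hand} \cdot 100$, positive when
the tool undercounts; per-image errors are binned into half-open 5-point
ranges $[0,5), [5,10), \dots$ with an overflow bin at 30.

## The synthetic assay simulator

`simulateImage()` renders a bright circular filter disc (default 2400 px,
a 13 mm disc at the ~192 px/mm scale implied by a 13 mm filter filling
most of a ~2500 px merged frame; the µm-per-px of the original rig is not
published) on a darker surround, and places:

* **Seeds** — dark ellipses, major axis 25–38 px (just under 200 µm at
  that scale), aspect 0.60–0.85, random orientation, non-overlapping
  centers (rejection sampling with bounded retries, default 100; real
  assays rarely overlap). Exactly `round(nSeeds)` per scene.
* **Radicles** — thin tapering curved polylines (length 20–120 px, width
  3–6 px) emerging from one pole of each germinated seed, kept inside the
  disc and clear of other seeds. The radicle-onset annotation is a square
  of side ≈ the seed's minor axis centered on the junction; onset boxes
  have no published size rule, only a location.
* **Debris** — irregular multi-lobed blobs whose size and contrast overlap
  the seeds (default 30 per image). Real debris statistics are not
  characterized anywhere; this model is parametric, not fitted.

Defaults are the study conditions: 50 seeds per filter, germination
fraction 0.40 — which makes the pooled seed:radicle annotation ratio
2.5:1, the class imbalance observed in the real training data. Ground
truth is exact by construction. `simulateDataset()` derives per-image
seeds from the master seed with a fixed Lehmer-style mixing function
(exact in doubles, hence platform-stable) and jitters per-image counts
(Poisson seeds, binomial germination) so dataset statistics have realistic
spread.

What the simulator does *not* emulate: glass-fibre texture, optical blur
and vignetting, staining variation, touching or stacked seeds, and
real debris morphology. Passing the recovery tests below therefore shows
the *pipeline arithmetic and post-processing* are correct, not that any
detector generalizes to real micrographs.

## The classical reference backend

`detectClassical()` makes the pipeline runnable without trained weights:
Otsu thresholds (computed on a strided pixel subsample) isolate the disc
and its dark objects; a morphological opening (disc kernel, radius 4 px —
wide enough to erase 6 px radicles, narrow enough to preserve 15 px seed
minor axes) separates seed bodies; connected components are filtered by
area (140–1700 px²; the band brackets the ellipse areas implied by the
default axis ranges) and eccentricity (≤ 0.95). Radicle onsets are thin
residuals (threshold minus opened image) of ≥ 35 px² attached to a
detected seed, at most one per seed. Pseudo-objectness is the normalized
margin of each component's shape scores, clipped to $[0.01, 0.99]$, so
threshold sweeps behave smoothly against this backend. It is a first-class
detector for synthetic scenes, and the contract any external grid-output
backend must meet (`readRawGrid()` + `decodeRaw()`).

## Numerical and design choices

* Internal box coordinates are 0-based half-open; Pascal-VOC XML is
  1-based inclusive ($x_{\min} = \mathrm{xmin} - 1$, $x_{\max} =
  \mathrm{xmax}$), Darknet text is normalized center/size. VOC round-trips
  are exact on integers; Darknet round-trips are within one pixel at six
  written decimals.
* Germination above 100 % (more radicle than seed detections — possible
  because classes are counted independently) is reported unclamped with a
  warning.
* Reported percentages and rates use two decimals, matching the precision
  of the published tables; internal values keep full precision.
  Pooled underestimation uses three decimals, again following the
  published table.
* The stitcher (`stitchPair()`) is translation-only: candidate overlaps
  are scored by normalized cross-correlation on a column-subsampled grid,
  near-ties favor the larger overlap, a minimum-new-content rule rejects
  the degenerate full-overlap solution, and a correlation floor of 0.5
  raises "no reliable overlap". The original workflow used interactive
  commercial photo merging; perspective mosaicking is out of scope.
* An image yielding zero seed detections reports `NA` germination (the
  source workflow never states this case).

## Problem sizes used in the checks

The acceptance checks run the full study-condition geometry: 50 simulated
2500 px scenes (debris 0, fixed seed) pushed end-to-end through the
classical backend at $P = 0.06$, expecting mean germination difference
≤ 2 points and exact per-image counts on ≥ 95 % of images; 1000 randomized
≤ 10-box suppression instances against the exhaustive oracle; 100 planted
two-cluster anchor recoveries within 5 %; and a constructed
false-positive ladder whose optimum $P = 0.06$ the sweep must find,
verified by full grid enumeration. Unit tests use the same seed geometry
in 600 px frames with ~10 seeds so the suite stays fast.

## Known limitations

* The classical backend is tuned to the simulator's contrast regime; on
  real micrographs it would need re-parameterized thresholds and would
  still not match a trained detector on debris discrimination.
* The published real-data accuracies (3.38-point test error and related
  figures) require the original trained weights and imagery and are not
  reproduced here; the evaluation machinery that produced them is.
* The decoder handles one grid scale per call; multi-scale outputs are
  concatenated by the caller.
* `germination_pct` treats radicle onsets as a count, so a radicle
  fragmented into several thin components still counts once per seed in
  the classical backend, but external backends must deduplicate via NMS.
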