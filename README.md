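# germVision

Automated counting of *Striga hermonthica* seed germination in glass-fibre
filter assay images.

## The problem

*Striga* is a root-parasitic weed devastating cereal production in
Sub-Saharan Africa and Southeast Asia. Screens for compounds or microbes
that stimulate suicidal germination (or suppress germination) are run as
filter assays: ~50 seeds on a 13 mm glass-fibre disc, imaged under a
dissecting microscope. Because the seeds are under 200 µm, scoring by hand
is the bottleneck. The readout per filter image is three numbers — total
seeds, radicle onsets (each emerging embryonic root marks one germinated
seed), and

```
germination % = 100 · n_radicle / n_seed
```

germVision implements the counting workflow as a testable R package:

* **Annotation handling** — Pascal-VOC (LabelImg) XML and Darknet-style
  normalized text, converted through one internal 0-based half-open box
  convention (`parseVoc()`, `writeVoc()`, `parseDarknetTxt()`,
  `writeDarknetTxt()`).
* **Detection machinery** — IoU (`iou()`), anchor derivation by K-means
  under the 1 − IoU shape distance (`kmeansAnchors()`, K = 9), decoding of
  S×S grid × 3-anchor detector output with sigmoid/exponential
  parameterization (`decodeRaw()`), objectness filtering at threshold P
  (`objectnessFilter()`, default operating point P = 0.06), class-wise
  greedy NMS (`nms()`, IoU 0.45), and letterboxing to the 608-px square
  input (`letterbox()`).
* **A classical reference backend** (`detectClassical()`) — thresholding,
  morphological opening, connected components with area/eccentricity
  filters, and thin-residual radicle detection — so the whole pipeline
  runs and is tested without trained network weights.
* **Quantification** — per-image counts (`countImage()`), the four-column
  results CSV (`writeCountsTable()`), overlay rendering with purple seed /
  bright-green radicle boxes (`renderOverlay()`), and the extended
  three-class summary arithmetic (`segmentationSummary()`).
* **Evaluation & model selection** — the average germination-difference
  metric (`avgGermDiff()`), pooled underestimation (`underestimationPct()`),
  error-range histograms (`errorHistogram()`), threshold and checkpoint
  sweeps (`sweepThreshold()`, `sweepCheckpoints()`), and comparison tables
  (`comparisonTable()`).
* **A synthetic assay simulator** (`simulateImage()`,
  `simulateDataset()`) — 2500-px scenes with a 13 mm disc at ~192 px/mm,
  elliptical seeds, curved tapering radicles, debris, and exact
  ground-truth annotations; plus a translation-only image-pair stitcher
  (`stitchPair()`) matching the two-shot capture of real filters.

See `vignettes/germination-counting.Rmd` for the methods account.

## Worked example

```r
library(germVision)

## three clean synthetic assays, written as PNGs
ds <- simulateDataset(simConfig(debrisDensity = 0), 3, rngSeed = 11)
for (sc in ds$scenes)
  writeAssayImage(sceneImage(sc), file.path("in", paste0(imageId(sc), ".png")))

## detect, count, and tabulate at the P = 0.06 operating point
cfg <- runConfig("in/*.png", "out", P = 0.06)
res <- runDetect(cfg)
```

The run logs one line per image and writes `out/results.csv` plus one
`*_annotated.png` overlay per input:

```
[INFO] sim_0001: 45 seeds, 14 radicle onsets
[INFO] sim_0002: 34 seeds, 11 radicle onsets
[INFO] sim_0003: 40 seeds, 16 radicle onsets
```

```
sample,total_seeds,germinated_seeds,germination_pct
sim_0001,45,14,31.11
sim_0002,34,11,32.35
sim_0003,40,16,40.00
```

Each row is one filter: 45 seeds were found on `sim_0001`, 14 of them
germinated (radicle onset detected), i.e. 31.11 % germination — here
matching the simulator's ground truth (`ds$manifest`) exactly. Validation
against a hand-count table and selection of the best threshold works the
same way through `runValidate(cfg, truth)`, which sweeps P = 0.01–0.10
and reports the minimizing threshold with per-class bias and an
error histogram.

A thin command-line front-end over these functions is installed at
`inst/exec/germvision.R` (subcommands `simulate`, `detect`, `validate`,
`stitch`, `anchors`).

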