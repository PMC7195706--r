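#' Average germination-difference metric
#'
#' The model-selection metric: the mean over images of the absolute
#' difference, in percentage points, between the predicted and the
#' hand-counted germination percentage. Image pairs are matched by sample
#' name; pairs where either side is undefined (no seeds) are excluded from
#' the mean and reported in an exclusion tally.
#'
#' @param predicted data.frame of \code{\link{countImage}} rows.
#' @param truth ground-truth table (\code{\link{groundTruthCounts}} or the
#'   same four-column layout).
#' @return Numeric value with attributes \code{nUsed} and \code{nExcluded}.
#' @examples
#' p <- data.frame(sample = c("a", "b"), totalSeeds = c(10, 10),
#'                 germinatedSeeds = c(2, 1), germinationPct = c(20, 10))
#' t <- data.frame(sample = c("a", "b"), nSeeds = c(10, 10),
#'                 nRadicles = c(2.5, 1.3), germinationPct = c(25, 13))
#' avgGermDiff(p, t) # 4
#' @export
avgGermDiff <- function(predicted, truth) {
    predPct <- .germColumn(predicted)
    truePct <- .germColumn(truth)
    m <- match(predicted$sample, truth$sample)
    ok <- !is.na(m)
    if (!any(ok)) stop("no overlapping samples between predictions and truth",
                       call. = FALSE)
    p <- predPct[ok]; t <- truePct[m[ok]]
    defined <- !is.na(p) & !is.na(t)
    out <- mean(abs(p[defined] - t[defined]))
    attr(out, "nUsed") <- sum(defined)
    attr(out, "nExcluded") <- sum(!defined)
    out
}

.germColumn <- function(d) {
    if (!is.null(d$germinationPct)) return(d$germinationPct)
    stop("table lacks a germinationPct column", call. = FALSE)
}

.classTotals <- function(d) {
    if (!is.null(d$totalSeeds))
        c(seed = sum(d$totalSeeds), radicle = sum(d$germinatedSeeds))
    else c(seed = sum(d$nSeeds), radicle = sum(d$nRadicles))
}

#' Underestimation percentage of a tool count against a hand count
#'
#' Signed relative error of pooled counts,
#' \code{(hand - tool) / hand * 100}: positive values mean the tool
#' undercounts. Reported to three decimals, matching the precision of the
#' published comparison table (4848 vs 4486 seeds gives 7.467 %; 910 vs 851
#' radicles gives 6.484 %). Overestimation comes out negative and is not
#' clamped.
#'
#' @param handTotal hand-counted total (> 0).
#' @param toolTotal tool-counted total.
#' @return Signed percentage, rounded to 3 decimals.
#' @examples
#' underestimationPct(4848, 4486) # 7.467
#' underestimationPct(910, 851)   # 6.484
#' @export
underestimationPct <- function(handTotal, toolTotal) {
    if (any(handTotal <= 0)) stop("handTotal must be > 0", call. = FALSE)
    round((handTotal - toolTotal) / handTotal * 100, 3)
}

#' Histogram of per-image counting errors
#'
#' Bins per-image absolute germination differences into half-open ranges
#' \code{[0,5), [5,10), ...} up to \code{maxEdge}, with an overflow bin
#' pooling everything at or above \code{maxEdge}, and reports each bin as a
#' percentage of images (summing to 100).
#'
#' @param perImageDiffs non-negative numeric vector, one value per image.
#' @param binWidth bin width in percentage points (default 5).
#' @param maxEdge upper edge of the regular bins (default 30).
#' @return data.frame with columns \code{bin} (label), \code{lower},
#'   \code{upper}, \code{pct}.
#' @export
errorHistogram <- function(perImageDiffs, binWidth = 5, maxEdge = 30) {
    if (length(perImageDiffs) == 0L)
        stop("no per-image differences supplied", call. = FALSE)
    if (any(perImageDiffs < 0)) stop("differences must be >= 0",
                                     call. = FALSE)
    lower <- seq(0, maxEdge - binWidth, by = binWidth)
    upper <- lower + binWidth
    counts <- vapply(seq_along(lower), function(i)
        sum(perImageDiffs >= lower[i] & perImageDiffs < upper[i]),
        numeric(1))
    over <- sum(perImageDiffs >= maxEdge)
    data.frame(
        bin = c(sprintf("[%g,%g)", lower, upper),
                sprintf(">=%g", maxEdge)),
        lower = c(lower, maxEdge), upper = c(upper, Inf),
        pct = c(counts, over) / length(perImageDiffs) * 100,
        stringsAsFactors = FALSE)
}

# per-image counts at threshold P from unfiltered detection sets
.countsAtP <- function(scoreSets, P, iouThreshold = 0.45) {
    do.call(rbind, lapply(names(scoreSets), function(nm)
        countImage(nm, nms(objectnessFilter(scoreSets[[nm]], P),
                           iouThreshold))))
}

.signedDeviation <- function(truth, counts) {
    handS <- .classTotals(truth)["seed"]
    handR <- .classTotals(truth)["radicle"]
    c(seed = if (handS > 0) as.numeric(
          underestimationPct(handS, sum(counts$totalSeeds))) else NA_real_,
      radicle = if (handR > 0) as.numeric(
          underestimationPct(handR, sum(counts$germinatedSeeds)))
          else NA_real_)
}

#' Sweep the objectness threshold P over a grid
#'
#' Re-applies the full post-processing chain (objectness filter at each P,
#' class-wise NMS, per-image counting) to unfiltered detection sets and
#' evaluates the average germination difference plus the signed per-class
#' deviation at every grid point. The P minimizing the metric is selected;
#' ties break toward the smallest P. The default grid (0.01 to 0.10 in
#' steps of 0.01) is the validation grid of the assay detector, on which
#' P = 0.06 is the published operating point.
#'
#' @param scoreSets named list (by sample) of unfiltered detection
#'   data.frames carrying objectness scores.
#' @param truth ground-truth counts table covering the samples.
#' @param grid numeric vector of thresholds.
#' @param iouThreshold NMS threshold applied after filtering.
#' @return A \code{\link{SweepResult}} (\code{what = "threshold"}).
#' @export
sweepThreshold <- function(scoreSets, truth,
                           grid = seq(0.01, 0.10, by = 0.01),
                           iouThreshold = 0.45) {
    if (length(grid) == 0L) stop("empty threshold grid", call. = FALSE)
    if (is.null(names(scoreSets)) || any(!nzchar(names(scoreSets))))
        stop("scoreSets must be a named list keyed by sample", call. = FALSE)
    rows <- lapply(grid, function(P) {
        counts <- .countsAtP(scoreSets, P, iouThreshold)
        dev <- .signedDeviation(truth, counts)
        data.frame(setting = P,
                   avgGermDiff = as.numeric(avgGermDiff(counts, truth)),
                   seedDeviation = dev["seed"],
                   radicleDeviation = dev["radicle"])
    })
    g <- do.call(rbind, rows)
    rownames(g) <- NULL
    sel <- g$setting[which.min(g$avgGermDiff)] # which.min takes first = smallest P
    new("SweepResult", grid = g, selected = sel, what = "threshold")
}

#' Sweep detector checkpoints at a fixed threshold
#'
#' Evaluates one detection set per training checkpoint at a fixed
#' objectness threshold (default P = 0.05, the threshold at which the
#' checkpoint sweep of the assay detector was run) and selects the
#' checkpoint minimizing the average germination difference; ties break
#' toward the earliest checkpoint in input order.
#'
#' @param checkpointOutputs named list (by checkpoint label) of named lists
#'   of unfiltered detection sets, one inner list per checkpoint.
#' @param truth ground-truth counts table.
#' @param P fixed objectness threshold.
#' @param iouThreshold NMS threshold.
#' @return A \code{\link{SweepResult}} (\code{what = "checkpoint"}).
#' @export
sweepCheckpoints <- function(checkpointOutputs, truth, P = 0.05,
                             iouThreshold = 0.45) {
    if (length(checkpointOutputs) == 0L)
        stop("no checkpoint outputs supplied", call. = FALSE)
    rows <- lapply(names(checkpointOutputs), function(lab) {
        counts <- .countsAtP(checkpointOutputs[[lab]], P, iouThreshold)
        dev <- .signedDeviation(truth, counts)
        data.frame(setting = lab,
                   avgGermDiff = as.numeric(avgGermDiff(counts, truth)),
                   seedDeviation = dev["seed"],
                   radicleDeviation = dev["radicle"],
                   stringsAsFactors = FALSE)
    })
    g <- do.call(rbind, rows)
    rownames(g) <- NULL
    sel <- g$setting[which.min(g$avgGermDiff)]
    new("SweepResult", grid = g, selected = sel, what = "checkpoint")
}

#' Hand-count versus tool comparison table
#'
#' Lays out pooled totals the way the published test comparison does:
#' rows hand-count, tool, and underestimation (%), over columns seeds,
#' radicles, average germination (%) and average difference per image
#' (percentage points; reported once, on the hand-count row).
#'
#' @param handTotals named vector or list with \code{seed} and
#'   \code{radicle} pooled hand counts; optionally \code{avgGermination}.
#' @param toolTotals same layout for the tool.
#' @param perImageDiffs optional per-image absolute germination
#'   differences; their mean fills the last column.
#' @return data.frame with rows \code{hand_count}, \code{tool},
#'   \code{underestimation_pct}.
#' @examples
#' comparisonTable(c(seed = 4848, radicle = 910),
#'                 c(seed = 4486, radicle = 851))
#' @export
comparisonTable <- function(handTotals, toolTotals, perImageDiffs = NULL) {
    h <- as.list(handTotals); t <- as.list(toolTotals)
    avgDiff <- if (is.null(perImageDiffs)) NA_real_ else
        mean(abs(perImageDiffs))
    data.frame(
        row = c("hand_count", "tool", "underestimation_pct"),
        seeds = c(h$seed, t$seed,
                  underestimationPct(h$seed, t$seed)),
        radicles = c(h$radicle, t$radicle,
                     underestimationPct(h$radicle, t$radicle)),
        avgGermination = c(
            if (is.null(h$avgGermination)) NA_real_ else h$avgGermination,
            if (is.null(t$avgGermination)) NA_real_ else t$avgGermination,
            NA_real_),
        avgDiffPerImage = c(avgDiff, NA_real_, NA_real_),
        stringsAsFactors = FALSE)
}

#' Build a full evaluation report
#'
#' Bundles the average germination difference, the signed per-class
#' deviation, the per-image error histogram, and the comparison table for a
#' set of predictions against hand counts at a stated operating point.
#'
#' @param predicted stacked \code{\link{countImage}} rows.
#' @param truth ground-truth counts table.
#' @param operatingPoint list, e.g. \code{list(model = "classical",
#'   P = 0.06)}.
#' @param binWidth,maxEdge histogram parameters (see
#'   \code{\link{errorHistogram}}).
#' @return An \code{\link{EvalReport}}.
#' @export
evalReport <- function(predicted, truth,
                       operatingPoint = list(model = "classical", P = 0.06),
                       binWidth = 5, maxEdge = 30) {
    m <- match(predicted$sample, truth$sample)
    if (anyNA(m))
        stop("truth table is missing samples: ",
             paste(predicted$sample[is.na(m)], collapse = ", "),
             call. = FALSE)
    agd <- avgGermDiff(predicted, truth)
    p <- .germColumn(predicted); t <- .germColumn(truth)[m]
    defined <- !is.na(p) & !is.na(t)
    diffs <- abs(p[defined] - t[defined])
    dev <- .signedDeviation(truth[m, , drop = FALSE], predicted)
    handGerm <- mean(t[defined])
    toolGerm <- mean(p[defined])
    cmp <- comparisonTable(
        c(.classTotals(truth[m, , drop = FALSE]),
          avgGermination = round(handGerm, 2)),
        c(.classTotals(predicted), avgGermination = round(toolGerm, 2)),
        diffs)
    new("EvalReport", avgGermDiff = as.numeric(agd),
        perClassDeviation = dev,
        histogram = errorHistogram(diffs, binWidth, maxEdge),
        nImages = as.integer(attr(agd, "nUsed")),
        nExcluded = as.integer(attr(agd, "nExcluded")),
        operatingPoint = operatingPoint, comparison = cmp)
}
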