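# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: suppression is solved by exhaustive subset
# search, binning and means by direct loops.

# Exhaustive-search suppression: enumerate all conflict-free subsets
# (no same-class pair with IoU above the threshold) and return the one
# maximizing the super-increasing weight sum 2^(n - objectness rank) --
# the lexicographically best conflict-free subset. Returns sorted row
# indices of the kept detections.
oracleSuppress <- function(dets, thr) {
    n <- nrow(dets)
    if (n == 0L) return(integer(0))
    if (n > 16L) stop("oracle is exponential; keep n small")
    area <- function(i) (dets$xMax[i] - dets$xMin[i]) *
        (dets$yMax[i] - dets$yMin[i])
    pairIou <- function(i, j) {
        iw <- min(dets$xMax[i], dets$xMax[j]) -
            max(dets$xMin[i], dets$xMin[j])
        ih <- min(dets$yMax[i], dets$yMax[j]) -
            max(dets$yMin[i], dets$yMin[j])
        if (iw <= 0 || ih <= 0) return(0)
        iw * ih / (area(i) + area(j) - iw * ih)
    }
    ms <- 0:(2^n - 1)
    valid <- rep(TRUE, length(ms))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (dets$class[i] == dets$class[j] && pairIou(i, j) > thr)
            valid <- valid & !(bitwAnd(ms, 2^(i - 1)) > 0 &
                               bitwAnd(ms, 2^(j - 1)) > 0)
    }
    rk <- rank(-dets$objectness, ties.method = "first")
    wt <- 2^(n - rk)
    score <- numeric(length(ms))
    for (i in seq_len(n))
        score <- score + wt[i] * (bitwAnd(ms, 2^(i - 1)) > 0)
    best <- ms[valid][which.max(score[valid])]
    which(bitwAnd(best, 2^(seq_len(n) - 1)) > 0)
}

# random detection instance for suppression tests; distinct objectness
randomDetections <- function(n, classes = c("seed", "radicle")) {
    x0 <- runif(n, 0, 10); y0 <- runif(n, 0, 10)
    w <- runif(n, 0.5, 4); h <- runif(n, 0.5, 4)
    detectionTable(
        data.frame(xMin = x0, yMin = y0, xMax = x0 + w, yMax = y0 + h,
                   label = sample(classes, n, replace = TRUE)),
        objectness = sample(seq(0.01, 0.99, length.out = 997), n))
}

# loop-written mean absolute difference over matched samples
oracleMeanAbsDiff <- function(pred, truth) {
    tot <- 0; k <- 0
    for (i in seq_len(nrow(pred))) {
        j <- which(truth$sample == pred$sample[i])
        p <- pred$germinationPct[i]; t <- truth$germinationPct[j]
        if (!is.na(p) && !is.na(t)) {
            tot <- tot + abs(p - t); k <- k + 1
        }
    }
    tot / k
}

# loop-written binning oracle matching the histogram contract
oracleHistogram <- function(diffs, binWidth = 5, maxEdge = 30) {
    nBins <- maxEdge / binWidth
    counts <- numeric(nBins + 1)
    for (d in diffs) {
        if (d >= maxEdge) counts[nBins + 1] <- counts[nBins + 1] + 1
        else {
            b <- floor(d / binWidth) + 1
            counts[b] <- counts[b] + 1
        }
    }
    counts / length(diffs) * 100
}

# small-but-default-geometry simulator config for unit tests: seeds keep
# their real pixel size, only the frame and the population shrink
testConfig <- function(...) {
    args <- utils::modifyList(
        list(imageSize = 600L, filterDiameter = 560, nSeeds = 10,
             germinationFraction = 0.5,
             radicleLengthRange = c(20, 60), debrisDensity = 0),
        list(...))
    do.call(simConfig, args)
}

# a detection table of well-separated square boxes of the given classes
spreadDetections <- function(labels, objectness, size = 20, gap = 60) {
    n <- length(labels)
    if (n == 0L) return(detectionTable(emptyBoxes(), numeric(0)))
    x0 <- (seq_len(n) - 1) * gap
    detectionTable(
        data.frame(xMin = x0, yMin = 0, xMax = x0 + size, yMax = size,
                   label = labels),
        objectness = objectness)
}
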