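#' Read an assay image as a grayscale matrix
#'
#' @param path PNG or JPEG file.
#' @return numeric matrix in [0, 1], rows = y.
#' @export
readAssayImage <- function(path) {
    img <- EBImage::readImage(path)
    if (EBImage::colorMode(img) == EBImage::Color)
        img <- EBImage::channel(img, "gray")
    # EBImage stores (x, y); transpose to rows = y
    t(EBImage::imageData(img))
}

#' Write a grayscale matrix or RGB array as a PNG file
#'
#' @param image numeric matrix (rows = y) or \code{c(rows, cols, 3)} array
#'   in [0, 1].
#' @param path destination .png path.
#' @return Invisibly, the path.
#' @export
writeAssayImage <- function(image, path) {
    png::writePNG(pmin(pmax(image, 0), 1), path)
    invisible(path)
}

#' Stitch a top/bottom image pair by translation-only alignment
#'
#' The two half-filter captures share an unknown band of rows; the stitcher
#' scans candidate overlaps (1 to \code{maxShift} rows), scores each by the
#' normalized cross-correlation between the bottom band of the top image
#' and the top band of the bottom image (on a column-subsampled grid), and
#' merges at the best-scoring overlap with a linear blending ramp across
#' the shared band. A perspective-free stand-in for interactive photo
#' merging: the capture rig translates the filter vertically between the
#' two shots.
#'
#' A candidate overlap is rejected when it would leave less than
#' \code{minNewContent} fresh rows from the bottom image (guards the
#' degenerate full-overlap solution on near-identical inputs), and the
#' whole stitch fails when the best correlation is below
#' \code{corFloor}.
#'
#' @param topImage,bottomImage numeric matrices of equal width.
#' @param maxShift largest candidate overlap in rows.
#' @param corFloor minimum acceptable correlation (default 0.5).
#' @param minNewContent minimum rows the bottom image must add.
#' @param colStride column subsampling stride for the correlation score.
#' @return list with \code{image} (merged matrix), \code{overlap} (rows)
#'   and \code{correlation}.
#' @export
stitchPair <- function(topImage, bottomImage, maxShift = 400L,
                       corFloor = 0.5, minNewContent = 50L,
                       colStride = 4L) {
    if (ncol(topImage) != ncol(bottomImage))
        stop("image pair must have equal widths", call. = FALSE)
    hT <- nrow(topImage); hB <- nrow(bottomImage)
    maxShift <- min(maxShift, hT, hB - minNewContent)
    if (maxShift < 1L)
        stop("no admissible overlap window", call. = FALSE)
    cols <- seq(1L, ncol(topImage), by = colStride)
    best <- c(overlap = NA_real_, cor = -Inf)
    for (o in seq_len(maxShift)) {
        aBand <- topImage[(hT - o + 1L):hT, cols, drop = FALSE]
        bBand <- bottomImage[seq_len(o), cols, drop = FALSE]
        sa <- stats::sd(aBand)
        if (sa == 0 || stats::sd(bBand) == 0) next
        cc <- stats::cor(as.vector(aBand), as.vector(bBand))
        # favor the largest-area consistent overlap among near-ties
        score <- cc - 1e-6 * (maxShift - o)
        if (is.finite(cc) && score > best["cor"]) {
            best <- c(overlap = o, cor = score)
        }
    }
    if (!is.finite(best["cor"]) || is.na(best["overlap"]) ||
        stats::cor(
            as.vector(topImage[(hT - best[["overlap"]] + 1L):hT, cols]),
            as.vector(bottomImage[seq_len(best[["overlap"]]), cols])) <
            corFloor)
        stop("no reliable overlap between the image pair", call. = FALSE)
    o <- as.integer(best[["overlap"]])
    merged <- matrix(0, hT + hB - o, ncol(topImage))
    merged[seq_len(hT - o), ] <- topImage[seq_len(hT - o), , drop = FALSE]
    merged[(hT + 1L):(hT + hB - o), ] <-
        bottomImage[(o + 1L):hB, , drop = FALSE]
    ramp <- seq(0, 1, length.out = o + 2L)[2:(o + 1L)]
    blend <- topImage[(hT - o + 1L):hT, , drop = FALSE] * (1 - ramp) +
        bottomImage[seq_len(o), , drop = FALSE] * ramp
    merged[(hT - o + 1L):hT, ] <- blend
    list(image = merged, overlap = o,
         correlation = as.numeric(stats::cor(
             as.vector(topImage[(hT - o + 1L):hT, cols]),
             as.vector(bottomImage[seq_len(o), cols]))))
}

#' Build a run configuration
#'
#' @param input character vector of image paths or glob patterns.
#' @param outputDir directory for the results table and overlays.
#' @param backend \code{"classical"} (the reference morphological detector)
#'   or \code{"raw-grids"} (decode externally produced grid outputs; each
#'   input is then a sidecar descriptor, see \code{\link{readRawGrid}}).
#' @param P objectness threshold (default 0.06, the selected operating
#'   point).
#' @param iouThreshold NMS IoU threshold (default 0.45).
#' @param rngSeed integer seed recorded with the run.
#' @param verbose logical; emit per-image log lines.
#' @param logFile optional path of a run log (appended).
#' @return A named list (class \code{"germVisionRunConfig"}).
#' @export
runConfig <- function(input, outputDir = ".",
                      backend = c("classical", "raw-grids"),
                      P = 0.06, iouThreshold = 0.45, rngSeed = 1L,
                      verbose = TRUE, logFile = NULL) {
    backend <- match.arg(backend)
    if (P < 0 || P > 1) stop("P must be in [0, 1]", call. = FALSE)
    structure(list(input = input, outputDir = outputDir, backend = backend,
                   P = P, iouThreshold = iouThreshold,
                   rngSeed = as.integer(rngSeed), verbose = verbose,
                   logFile = logFile),
              class = "germVisionRunConfig")
}

.logLine <- function(config, level, fmt, ...) {
    msg <- sprintf("[%s] %s %s", level,
                   format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    if (isTRUE(config$verbose)) message(msg)
    if (!is.null(config$logFile))
        cat(msg, "\n", file = config$logFile, append = TRUE)
    invisible(msg)
}

.resolveInputs <- function(input) {
    paths <- unlist(lapply(input, function(p) {
        if (file.exists(p)) p else Sys.glob(p)
    }))
    unique(paths)
}

# unfiltered detections for one input under the configured backend
.backendDetect <- function(path, config, anchorSetForRaw = NULL) {
    if (config$backend == "classical") {
        img <- readAssayImage(path)
        list(dets = detectClassical(img), image = img)
    } else {
        g <- readRawGrid(path)
        aset <- if (is.null(anchorSetForRaw)) trainingRecipe()@anchors
                else anchorSetForRaw
        list(dets = decodeRaw(g$raw, aset, g$resolution), image = NULL)
    }
}

#' Run detection over a set of images
#'
#' The tool's main entry point: for every input image, run the configured
#' backend, apply the objectness filter at \code{P} and class-wise NMS,
#' count seeds and radicle onsets, write a \code{"_annotated"} overlay PNG,
#' and finally write the four-column results table atomically
#' (\code{results.csv} in the output directory). Unreadable inputs are
#' skipped with a logged warning; the run is reproducible from (config,
#' seed).
#'
#' @param config a \code{\link{runConfig}}.
#' @param writeOverlays logical; write the per-image annotated PNGs.
#' @return Invisibly, the results data.frame (stacked
#'   \code{\link{countImage}} rows).
#' @export
runDetect <- function(config, writeOverlays = TRUE) {
    paths <- .resolveInputs(config$input)
    if (length(paths) == 0L)
        stop("no input images matched", call. = FALSE)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    results <- list()
    for (p in paths) {
        t0 <- proc.time()[["elapsed"]]
        got <- tryCatch(.backendDetect(p, config), error = function(e) e)
        if (inherits(got, "error")) {
            .logLine(config, "WARN", "skipping unreadable input %s (%s)",
                     p, conditionMessage(got))
            next
        }
        dets <- nms(objectnessFilter(got$dets, config$P),
                    config$iouThreshold)
        stem <- sub("\\.[A-Za-z0-9]+$", "", basename(p))
        res <- countImage(stem, dets)
        results[[stem]] <- res
        if (writeOverlays && !is.null(got$image))
            writeAssayImage(renderOverlay(got$image, dets),
                            file.path(config$outputDir,
                                      paste0(stem, "_annotated.png")))
        .logLine(config, "INFO",
                 "%s: %d seeds, %d radicle onsets (%.2f s)", stem,
                 res$totalSeeds, res$germinatedSeeds,
                 proc.time()[["elapsed"]] - t0)
    }
    if (length(results) == 0L)
        stop("no input image could be processed", call. = FALSE)
    out <- do.call(rbind, results)
    rownames(out) <- NULL
    writeCountsTable(out, file.path(config$outputDir, "results.csv"))
    invisible(out)
}

#' Validate a configuration against a hand-count table
#'
#' Runs the configured backend unfiltered over the inputs, sweeps the
#' objectness threshold over the validation grid, and reports the selected
#' operating point together with the error histogram and the hand-count
#' comparison table at that point.
#'
#' @param config a \code{\link{runConfig}}.
#' @param truth ground-truth counts table (see
#'   \code{\link{groundTruthCounts}}); must cover every input image by
#'   sample name.
#' @param grid threshold grid for \code{\link{sweepThreshold}}.
#' @return list with \code{report} (an \code{\link{EvalReport}} at the
#'   selected P) and \code{sweep} (the \code{\link{SweepResult}}).
#' @export
runValidate <- function(config, truth,
                        grid = seq(0.01, 0.10, by = 0.01)) {
    paths <- .resolveInputs(config$input)
    if (length(paths) == 0L) stop("no input images matched", call. = FALSE)
    scoreSets <- list()
    for (p in paths) {
        stem <- sub("\\.[A-Za-z0-9]+$", "", basename(p))
        scoreSets[[stem]] <- .backendDetect(p, config)$dets
    }
    missing <- setdiff(names(scoreSets), truth$sample)
    if (length(missing))
        stop("truth table is missing samples: ",
             paste(missing, collapse = ", "), call. = FALSE)
    sweep <- sweepThreshold(scoreSets, truth, grid = grid,
                            iouThreshold = config$iouThreshold)
    bestP <- selectedSetting(sweep)
    counts <- .countsAtP(scoreSets, bestP, config$iouThreshold)
    report <- evalReport(counts, truth,
                         operatingPoint = list(model = config$backend,
                                               P = bestP))
    .logLine(config, "INFO",
             "selected P = %.2f (avg germination difference %.3f)", bestP,
             avgGermDiffValue(report))
    list(report = report, sweep = sweep)
}
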