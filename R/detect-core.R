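#' Build a detection table
#'
#' Detections are kept as a data.frame with the box columns (\code{xMin},
#' \code{yMin}, \code{xMax}, \code{yMax}), an \code{objectness} confidence
#' in [0, 1], per-class probabilities \code{pSeed} and \code{pRadicle}
#' (class-independent sigmoid outputs, each in [0, 1]), and the
#' \code{class} label (argmax over the class probabilities).
#'
#' @param boxes data.frame of boxes (label column optional; recomputed from
#'   the probabilities when \code{pSeed}/\code{pRadicle} are given).
#' @param objectness numeric vector in [0, 1].
#' @param pSeed,pRadicle class probabilities; default degenerate (1/0 for a
#'   labelled box table).
#' @return A detection data.frame.
#' @export
detectionTable <- function(boxes, objectness, pSeed = NULL, pRadicle = NULL) {
    n <- nrow(boxes)
    stopifnot(length(objectness) == n)
    if (any(objectness < 0 | objectness > 1))
        stop("objectness must be in [0, 1]", call. = FALSE)
    if (is.null(pSeed)) pSeed <- as.numeric(boxes$label == "seed")
    if (is.null(pRadicle)) pRadicle <- as.numeric(boxes$label == "radicle")
    cls <- ifelse(pSeed >= pRadicle, "seed", "radicle")
    if (!is.null(boxes$label)) cls <- as.character(boxes$label)
    d <- data.frame(xMin = boxes$xMin, yMin = boxes$yMin,
                    xMax = boxes$xMax, yMax = boxes$yMax,
                    objectness = objectness, pSeed = pSeed,
                    pRadicle = pRadicle, class = cls,
                    stringsAsFactors = FALSE)
    rownames(d) <- NULL
    d
}

.emptyDetections <- function() {
    detectionTable(emptyBoxes(), numeric(0), numeric(0), numeric(0))
}

#' Intersection over union of two boxes
#'
#' The standard overlap score between axis-aligned boxes: intersection area
#' divided by union area, 0 for disjoint boxes and 1 only for identical
#' boxes.
#'
#' @param a,b boxes given as \code{c(xMin, yMin, xMax, yMax)} or one-row
#'   data.frames with those columns.
#' @return A number in [0, 1].
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
    a <- .asBoxVec(a); b <- .asBoxVec(b)
    iw <- min(a[3], b[3]) - max(a[1], b[1])
    ih <- min(a[4], b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

.asBoxVec <- function(b) {
    if (is.data.frame(b)) b <- unlist(b[1, c("xMin", "yMin", "xMax", "yMax")])
    b <- as.numeric(b)
    if (length(b) != 4L || b[1] >= b[3] || b[2] >= b[4])
        stop("a box is c(xMin, yMin, xMax, yMax) with positive extent",
             call. = FALSE)
    b
}

#' Pairwise IoU matrix between two box tables
#'
#' @param a,b data.frames with box columns.
#' @return \code{nrow(a) x nrow(b)} matrix of IoU values.
#' @export
iouMatrix <- function(a, b) {
    n <- nrow(a); m <- nrow(b)
    iw <- pmin(outer(a$xMax, b$xMax, pmin) - outer(a$xMin, b$xMin, pmax),
               Inf)
    ih <- outer(a$yMax, b$yMax, pmin) - outer(a$yMin, b$yMin, pmax)
    iw[iw < 0] <- 0; ih[ih < 0] <- 0
    inter <- iw * ih
    areaA <- (a$xMax - a$xMin) * (a$yMax - a$yMin)
    areaB <- (b$xMax - b$xMin) * (b$yMax - b$yMin)
    un <- outer(areaA, areaB, "+") - inter
    out <- inter / un
    dim(out) <- c(n, m)
    out
}

# 1 - IoU between center-aligned shapes: rows of wh1 vs rows of wh2
.shapeDist <- function(wh1, wh2) {
    iw <- outer(wh1[, 1], wh2[, 1], pmin)
    ih <- outer(wh1[, 2], wh2[, 2], pmin)
    inter <- iw * ih
    un <- outer(wh1[, 1] * wh1[, 2], wh2[, 1] * wh2[, 2], "+") - inter
    1 - inter / un
}

#' Derive anchor boxes by K-means over annotated box shapes
#'
#' Clusters the (width, height) shapes of training boxes into K anchor
#' shapes, the priors a grid-and-anchor detector decodes against. The
#' clustering distance is the convention introduced for anchor derivation:
#' \code{1 - IoU} between the two shapes aligned at a common center, so
#' large and small boxes are treated on a relative scale. Plain Euclidean
#' distance on (w, h) is available via \code{distance = "euclidean"}
#' (delegated to \code{\link[stats]{kmeans}}).
#'
#' Lloyd iterations (assignment, then mean-shape update) run until the
#' assignment stabilizes or \code{maxIter} is reached; the mean within-cluster
#' distance is recorded per iteration (attribute \code{"objective"} of the
#' result) and the iteration stops, keeping the previous representatives, if
#' an update would increase it. Empty clusters are reseeded with the box
#' farthest from its representative. Deterministic given \code{rngSeed}.
#'
#' @param boxes data.frame with box columns (or a 2-column matrix of widths
#'   and heights).
#' @param K number of anchors (default 9).
#' @param rngSeed integer seed for the initialization.
#' @param distance \code{"iou"} (default) or \code{"euclidean"}.
#' @param maxIter iteration cap (default 300).
#' @param inputResolution resolution recorded on the resulting
#'   \code{\link{AnchorSet}}.
#' @return An \code{\link{AnchorSet}} with attribute \code{"objective"}, the
#'   per-iteration mean 1 - IoU (for the IoU distance).
#' @export
kmeansAnchors <- function(boxes, K = 9L, rngSeed = 1L,
                          distance = c("iou", "euclidean"),
                          maxIter = 300L, inputResolution = 608) {
    distance <- match.arg(distance)
    wh <- if (is.matrix(boxes)) boxes else
        cbind(boxes$xMax - boxes$xMin, boxes$yMax - boxes$yMin)
    if (nrow(wh) == 0L) stop("no boxes supplied", call. = FALSE)
    if (any(wh <= 0)) stop("box shapes must be positive", call. = FALSE)
    uniq <- unique(round(wh, 9))
    if (nrow(uniq) < K)
        stop(sprintf("only %d distinct box shapes for K = %d clusters",
                     nrow(uniq), K), call. = FALSE)
    if (distance == "euclidean") {
        km <- withr::with_seed(rngSeed,
            stats::kmeans(wh, centers = K, nstart = 5, iter.max = maxIter))
        return(anchorSet(km$centers, inputResolution))
    }
    withr::with_seed(rngSeed, {
        reps <- uniq[sample.int(nrow(uniq), K), , drop = FALSE]
        assign <- rep(0L, nrow(wh))
        objective <- numeric(0)
        for (it in seq_len(maxIter)) {
            d <- .shapeDist(wh, reps)
            newAssign <- max.col(-d, ties.method = "first")
            obj <- mean(d[cbind(seq_len(nrow(wh)), newAssign)])
            if (length(objective) && obj > objective[length(objective)] + 1e-12)
                break
            objective <- c(objective, obj)
            if (identical(newAssign, assign)) break
            assign <- newAssign
            newReps <- reps
            for (k in seq_len(K)) {
                members <- wh[assign == k, , drop = FALSE]
                if (nrow(members) == 0L) {
                    # reseed an empty cluster with the worst-fitting box
                    worst <- which.max(d[cbind(seq_len(nrow(wh)), assign)])
                    newReps[k, ] <- wh[worst, ]
                } else {
                    newReps[k, ] <- colMeans(members)
                }
            }
            reps <- newReps
        }
        out <- anchorSet(reps, inputResolution)
        attr(out, "objective") <- objective
        out
    })
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Decode a raw grid-and-anchor detector output
#'
#' A single-scale detector output is an S x S grid of cells, each carrying
#' A anchors with 4 box parameters (tx, ty, tw, th), an objectness logit and
#' per-class logits. Decoding follows the standard parameterization: the box
#' center is \code{(col + sigmoid(tx), row + sigmoid(ty)) * stride} with
#' \code{stride = inputResolution / S}; the box size is the anchor shape
#' scaled by \code{exp(tw), exp(th)}; objectness and class probabilities are
#' sigmoids of their logits. No filtering happens here — exactly
#' \code{S * S * A} detections are returned, in cell-major (row, column,
#' anchor) order; apply \code{\link{objectnessFilter}} and \code{\link{nms}}
#' downstream. Multi-scale detectors call this once per scale and
#' concatenate.
#'
#' @param raw numeric array of dim \code{c(S, S, A, 5 + nClasses)}; the last
#'   margin is \code{(tx, ty, tw, th, objectness, class logits...)}. Rows
#'   index y, columns x.
#' @param anchorSet an \code{\link{AnchorSet}} whose first A anchors match
#'   the grid (pixel units at \code{inputResolution}).
#' @param inputResolution network input resolution (defaults to the anchor
#'   set's).
#' @return A detection data.frame in input-resolution coordinates.
#' @export
decodeRaw <- function(raw, anchorSet, inputResolution = NULL) {
    stopifnot(is(anchorSet, "AnchorSet"))
    if (is.null(inputResolution)) inputResolution <- anchorSet@inputResolution
    dims <- dim(raw)
    if (length(dims) != 4L || dims[1] != dims[2])
        stop("raw must be an S x S x A x (5 + C) array", call. = FALSE)
    S <- dims[1]; A <- dims[3]; C <- dims[4] - 5L
    if (C < 2L) stop("raw must carry at least two class logits", call. = FALSE)
    wh <- anchors(anchorSet)
    if (nrow(wh) < A)
        stop(sprintf("anchor set has %d shapes but the grid uses %d",
                     nrow(wh), A), call. = FALSE)
    stride <- inputResolution / S
    # cell-major order: row i, col j, anchor a
    idx <- expand.grid(a = seq_len(A), j = seq_len(S), i = seq_len(S))
    idx <- idx[order(idx$i, idx$j, idx$a), ]
    flat <- function(k) raw[cbind(idx$i, idx$j, idx$a, k)]
    cx <- (idx$j - 1 + .sigmoid(flat(1L))) * stride
    cy <- (idx$i - 1 + .sigmoid(flat(2L))) * stride
    bw <- wh[idx$a, 1] * exp(flat(3L))
    bh <- wh[idx$a, 2] * exp(flat(4L))
    obj <- .sigmoid(flat(5L))
    pSeed <- .sigmoid(flat(6L))
    pRadicle <- .sigmoid(flat(7L))
    detectionTable(data.frame(xMin = cx - bw / 2, yMin = cy - bh / 2,
                              xMax = cx + bw / 2, yMax = cy + bh / 2),
                   obj, pSeed, pRadicle)
}

#' Filter detections by objectness threshold
#'
#' Keeps detections whose objectness confidence is at least \code{P}
#' (inclusive); everything below the threshold is discarded. \code{P} is the
#' operating threshold swept during validation (grid 0.01-0.10); the
#' selected default operating point downstream is \code{P = 0.06}.
#' Input order is preserved.
#'
#' @param dets detection data.frame.
#' @param P threshold in [0, 1].
#' @return The retained detections.
#' @export
objectnessFilter <- function(dets, P) {
    if (length(P) != 1L || is.na(P) || P < 0 || P > 1)
        stop("P must be a single value in [0, 1]", call. = FALSE)
    dets[dets$objectness >= P, , drop = FALSE]
}

#' Class-wise greedy non-maximum suppression
#'
#' Standard companion of the decoder: detections are visited in order of
#' descending objectness and a detection is removed when it overlaps an
#' already-retained detection of the same class with IoU strictly greater
#' than \code{iouThreshold}. Overlaps across classes (a radicle-onset box on
#' top of its seed) are never suppressed.
#'
#' @param dets detection data.frame.
#' @param iouThreshold suppression threshold in (0, 1); default 0.45.
#' @return The retained detections, ordered by descending objectness within
#'   the original's stable order.
#' @export
nms <- function(dets, iouThreshold = 0.45) {
    if (iouThreshold <= 0 || iouThreshold >= 1)
        stop("iouThreshold must be in (0, 1)", call. = FALSE)
    if (nrow(dets) <= 1L) return(dets)
    keep <- logical(nrow(dets))
    ord <- order(-dets$objectness)
    for (cls in unique(dets$class)) {
        cand <- ord[dets$class[ord] == cls]
        kept <- integer(0)
        for (i in cand) {
            if (length(kept) == 0L) { kept <- i; keep[i] <- TRUE; next }
            ious <- iouMatrix(dets[i, , drop = FALSE],
                              dets[kept, , drop = FALSE])
            if (all(ious <= iouThreshold)) { kept <- c(kept, i); keep[i] <- TRUE }
        }
    }
    dets[sort(which(keep)), , drop = FALSE]
}

#' Letterbox an image to the network input resolution
#'
#' Aspect-preserving resize onto a square canvas with neutral-gray padding,
#' the standard pre-processing of square-input detectors. Returns the
#' resized canvas together with the affine transform needed to map boxes
#' back to the original frame with \code{\link{unmapBoxes}}.
#'
#' @param image numeric matrix (rows = y) in [0, 1].
#' @param inputResolution target square side (default 608).
#' @param fill padding gray level (default 0.5).
#' @return list with \code{image} (the \code{inputResolution}-square matrix)
#'   and \code{transform} (list \code{scale}, \code{padX}, \code{padY}).
#' @export
letterbox <- function(image, inputResolution = 608, fill = 0.5) {
    if (inputResolution <= 0) stop("inputResolution must be positive",
                                   call. = FALSE)
    h <- nrow(image); w <- ncol(image)
    scale <- inputResolution / max(w, h)
    newW <- round(w * scale); newH <- round(h * scale)
    # EBImage's first array dimension is our row (y) axis
    resized <- EBImage::imageData(EBImage::resize(
        EBImage::Image(image), w = newH, h = newW))
    canvas <- matrix(fill, inputResolution, inputResolution)
    padX <- floor((inputResolution - newW) / 2)
    padY <- floor((inputResolution - newH) / 2)
    canvas[padY + seq_len(newH), padX + seq_len(newW)] <- resized
    list(image = canvas,
         transform = list(scale = scale, padX = padX, padY = padY))
}

#' Map letterboxed boxes back to the original image frame
#'
#' Inverts the \code{\link{letterbox}} transform; the round trip moves box
#' corners by at most one pixel (the resize quantization).
#'
#' @param boxes data.frame with box columns in letterbox coordinates.
#' @param transform the transform returned by \code{\link{letterbox}}.
#' @return The boxes in original-image coordinates (other columns passed
#'   through).
#' @export
unmapBoxes <- function(boxes, transform) {
    out <- boxes
    out$xMin <- (boxes$xMin - transform$padX) / transform$scale
    out$xMax <- (boxes$xMax - transform$padX) / transform$scale
    out$yMin <- (boxes$yMin - transform$padY) / transform$scale
    out$yMax <- (boxes$yMax - transform$padY) / transform$scale
    out
}

#' Map original-frame boxes into letterbox coordinates
#'
#' @param boxes data.frame with box columns.
#' @param transform the transform returned by \code{\link{letterbox}}.
#' @return The boxes in letterbox coordinates.
#' @export
mapBoxes <- function(boxes, transform) {
    out <- boxes
    out$xMin <- boxes$xMin * transform$scale + transform$padX
    out$xMax <- boxes$xMax * transform$scale + transform$padX
    out$yMin <- boxes$yMin * transform$scale + transform$padY
    out$yMax <- boxes$yMax * transform$scale + transform$padY
    out
}

#' Default training recipe
#'
#' @param anchorSet optional \code{\link{AnchorSet}} to attach; defaults to
#'   a generic 9-anchor set.
#' @return A \code{\link{TrainingRecipe}} with the assay detector's
#'   settings (see \code{\link{TrainingRecipe-class}}).
#' @export
trainingRecipe <- function(anchorSet = NULL) {
    if (is.null(anchorSet))
        anchorSet <- anchorSet(cbind(
            w = c(10, 16, 33, 30, 62, 59, 116, 156, 373),
            h = c(13, 30, 23, 61, 45, 119, 90, 198, 326)))
    new("TrainingRecipe", optimizer = "sgd", momentum = 0.9,
        learningRate = 1e-3, weightDecay = 5e-4, maxEpochs = 20000L,
        lrDropEpochs = c(16000L, 18000L), lrDropFactor = 10,
        inputResolution = 608L,
        augmentation = c("hsv_shift", "horizontal_flip", "jitter"),
        anchors = anchorSet)
}

#' Serialize / read a training recipe as a YAML config document
#'
#' \code{writeTrainingRecipe} renders the recipe as a key-value document
#' (optionally written to a file); \code{readTrainingRecipe} is its exact
#' inverse, validating the values on the way in.
#'
#' @param recipe a \code{\link{TrainingRecipe}}.
#' @param path optional file path.
#' @return \code{writeTrainingRecipe}: YAML text (invisibly when written to
#'   a file); \code{readTrainingRecipe}: a \code{TrainingRecipe}.
#' @export
writeTrainingRecipe <- function(recipe, path = NULL) {
    stopifnot(is(recipe, "TrainingRecipe"))
    doc <- list(optimizer = recipe@optimizer, momentum = recipe@momentum,
                learning_rate = recipe@learningRate,
                weight_decay = recipe@weightDecay,
                max_epochs = recipe@maxEpochs,
                lr_drop_epochs = as.list(recipe@lrDropEpochs),
                lr_drop_factor = recipe@lrDropFactor,
                input_resolution = recipe@inputResolution,
                augmentation = as.list(recipe@augmentation),
                anchors = lapply(seq_len(nrow(recipe@anchors@anchors)),
                                 function(i) as.list(
                                     recipe@anchors@anchors[i, ])),
                anchor_input_resolution = recipe@anchors@inputResolution)
    txt <- yaml::as.yaml(doc)
    if (!is.null(path)) {
        writeLines(txt, path)
        return(invisible(txt))
    }
    txt
}

#' @rdname writeTrainingRecipe
#' @param doc YAML text or a path to a YAML file.
#' @export
readTrainingRecipe <- function(doc) {
    lst <- if (length(doc) == 1L && !grepl("\n", doc) && file.exists(doc))
        yaml::read_yaml(doc) else yaml::yaml.load(paste(doc, collapse = "\n"))
    wh <- do.call(rbind, lapply(lst$anchors, function(a)
        c(w = as.numeric(a$w), h = as.numeric(a$h))))
    new("TrainingRecipe", optimizer = lst$optimizer,
        momentum = as.numeric(lst$momentum),
        learningRate = as.numeric(lst$learning_rate),
        weightDecay = as.numeric(lst$weight_decay),
        maxEpochs = as.integer(lst$max_epochs),
        lrDropEpochs = as.integer(unlist(lst$lr_drop_epochs)),
        lrDropFactor = as.numeric(lst$lr_drop_factor),
        inputResolution = as.integer(lst$input_resolution),
        augmentation = as.character(unlist(lst$augmentation)),
        anchors = anchorSet(wh, as.numeric(lst$anchor_input_resolution)))
}

#' Write a raw output grid as a values file plus sidecar descriptor
#'
#' Inverse of \code{\link{readRawGrid}}; used to hand raw grids between an
#' external detector back-end and this package.
#'
#' @param raw numeric array of dim \code{c(S, S, A, 5 + C)}.
#' @param sidecarPath path for the YAML descriptor; the values file is
#'   written next to it with extension \code{.values.txt}.
#' @param resolution network input resolution to record.
#' @return Invisibly, the sidecar path.
#' @export
writeRawGrid <- function(raw, sidecarPath, resolution = 608) {
    dims <- dim(raw)
    stopifnot(length(dims) == 4L, dims[1] == dims[2])
    S <- dims[1]; A <- dims[3]; C <- dims[4] - 5L
    vf <- sub("\\.ya?ml$", "", sidecarPath)
    vf <- paste0(basename(vf), ".values.txt")
    # cell-major (i, j, a, channel-fastest) ordering
    v <- aperm(raw, c(4, 3, 2, 1))
    writeLines(paste(format(as.vector(v), scientific = FALSE, trim = TRUE),
                     collapse = " "),
               file.path(dirname(sidecarPath), vf))
    yaml::write_yaml(list(s = S, anchors_per_cell = A, classes = C,
                          resolution = resolution, values_file = vf),
                     sidecarPath)
    invisible(sidecarPath)
}

#' Read a raw output grid from a values file plus sidecar descriptor
#'
#' External detector back-ends hand over one raw grid per scale as a flat
#' values file with a small YAML sidecar describing its shape. The sidecar
#' holds \code{s} (grid side), \code{anchors_per_cell}, \code{classes},
#' \code{resolution} and \code{values_file} (relative to the sidecar).
#' Values are whitespace-separated numbers in cell-major order: for row i,
#' column j, anchor a, the 5 + classes channel values
#' (tx, ty, tw, th, objectness logit, class logits).
#'
#' @param sidecarPath path to the YAML descriptor.
#' @return list with \code{raw} (the array for \code{\link{decodeRaw}}),
#'   \code{resolution}, and the descriptor fields.
#' @export
readRawGrid <- function(sidecarPath) {
    dsc <- yaml::read_yaml(sidecarPath)
    S <- as.integer(dsc$s); A <- as.integer(dsc$anchors_per_cell)
    C <- as.integer(dsc$classes)
    vf <- file.path(dirname(sidecarPath), dsc$values_file)
    v <- scan(vf, quiet = TRUE)
    want <- S * S * A * (5L + C)
    if (length(v) != want)
        stop(sprintf("values file has %d numbers, expected %d",
                     length(v), want), call. = FALSE)
    raw <- array(0, dim = c(S, S, A, 5L + C))
    # values are cell-major (i, j, a, channel); fill accordingly
    v <- array(v, dim = c(5L + C, A, S, S))
    for (k in seq_len(5L + C))
        raw[, , , k] <- aperm(v[k, , , , drop = TRUE], c(3, 2, 1))
    list(raw = raw, resolution = as.numeric(dsc$resolution),
         s = S, anchorsPerCell = A, classes = C)
}
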