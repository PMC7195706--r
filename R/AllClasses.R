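#' @import methods
NULL

#' Class vocabulary for annotations and detections
#'
#' The two-class annotation scheme of the filter assay (seeds and radicle
#' onsets, i.e. germinated seeds), plus \code{"haustorium"} reserved for the
#' extended three-class system.
#'
#' @return Character vector of the accepted class labels, in index order
#'   (Darknet class indices 0, 1, 2).
#' @examples
#' classLabels()
#' @export
classLabels <- function() c("seed", "radicle", "haustorium")

.validBoxes <- function(boxes, width = NULL, height = NULL) {
    req <- c("xMin", "yMin", "xMax", "yMax", "label")
    if (!is.data.frame(boxes) || !all(req %in% names(boxes)))
        return(sprintf("boxes must be a data.frame with columns %s",
                       paste(req, collapse = ", ")))
    if (nrow(boxes) == 0L) return(TRUE)
    num <- c("xMin", "yMin", "xMax", "yMax")
    if (!all(vapply(boxes[num], is.numeric, logical(1))))
        return("box coordinates must be numeric")
    if (!all(is.finite(as.matrix(boxes[num]))))
        return("box coordinates must be finite")
    if (any(boxes$xMin < 0) || any(boxes$yMin < 0))
        return("box coordinates must be >= 0")
    if (any(boxes$xMin >= boxes$xMax) || any(boxes$yMin >= boxes$yMax))
        return("boxes must satisfy xMin < xMax and yMin < yMax")
    bad <- !boxes$label %in% classLabels()
    if (any(bad))
        return(sprintf("unknown class label(s): %s (accepted: %s)",
                       paste(unique(boxes$label[bad]), collapse = ", "),
                       paste(classLabels(), collapse = ", ")))
    if (!is.null(width)) {
        out <- boxes$xMax > width | boxes$yMax > height
        if (any(out))
            return(sprintf("box %d lies outside the %g x %g image",
                           which(out)[1L], width, height))
    }
    TRUE
}

#' ImageAnnotation: bounding-box ground truth for one assay image
#'
#' Holds the image identifier, the pixel dimensions, and a table of
#' axis-aligned boxes in the package's internal coordinate convention:
#' 0-based, half-open intervals \eqn{[xMin, xMax) \times [yMin, yMax)} in
#' pixel units. Pascal-VOC XML (1-based inclusive) and Darknet text
#' (normalized center/size) are converted to and from this hub convention by
#' \code{\link{parseVoc}}, \code{\link{writeVoc}},
#' \code{\link{parseDarknetTxt}} and \code{\link{writeDarknetTxt}}.
#'
#' @slot imageId character image identifier (typically the file stem).
#' @slot width,height integer pixel dimensions, positive.
#' @slot boxes data.frame with columns \code{xMin}, \code{yMin}, \code{xMax},
#'   \code{yMax} (pixels) and \code{label} (one of \code{\link{classLabels}}).
#'
#' @seealso \code{\link{imageAnnotation}} (constructor), \code{\link{boxes}}
#' @name ImageAnnotation-class
#' @aliases ImageAnnotation
#' @exportClass ImageAnnotation
setClass("ImageAnnotation",
    representation(imageId = "character", width = "integer",
                   height = "integer", boxes = "data.frame"),
    validity = function(object) {
        if (length(object@imageId) != 1L) return("imageId must be length 1")
        if (length(object@width) != 1L || length(object@height) != 1L ||
            object@width < 1L || object@height < 1L)
            return("width and height must be positive scalars")
        .validBoxes(object@boxes, object@width, object@height)
    })

#' Construct an ImageAnnotation
#'
#' @param imageId image identifier.
#' @param width,height image dimensions in pixels.
#' @param boxes data.frame of boxes (see \code{\link{ImageAnnotation-class}});
#'   defaults to an empty table.
#' @return An \code{ImageAnnotation} object.
#' @examples
#' ann <- imageAnnotation("img1", 100, 100,
#'   data.frame(xMin = 10, yMin = 10, xMax = 40, yMax = 35, label = "seed"))
#' nBoxes(ann)
#' @export
imageAnnotation <- function(imageId, width, height, boxes = emptyBoxes()) {
    rownames(boxes) <- NULL
    new("ImageAnnotation", imageId = as.character(imageId),
        width = as.integer(width), height = as.integer(height),
        boxes = boxes)
}

#' Empty box table
#'
#' @return A zero-row data.frame with the box columns.
#' @export
emptyBoxes <- function() {
    data.frame(xMin = numeric(0), yMin = numeric(0), xMax = numeric(0),
               yMax = numeric(0), label = character(0),
               stringsAsFactors = FALSE)
}

#' SimConfig: parameters of the synthetic filter-assay simulator
#'
#' The defaults emulate the standard glass-fibre germination assay as imaged
#' on a dissecting microscope: a 13 mm filter disc filling most of a ~2500 px
#' square frame (about 192 px/mm), an average of 50 Striga seeds per filter,
#' seeds just under 200 um across, and thin curved radicles emerging from
#' germinated seeds.
#'
#' @slot imageSize square image side, pixels.
#' @slot filterDiameter filter-disc diameter, pixels (13 mm at ~192 px/mm).
#' @slot nSeeds mean number of seeds per image.
#' @slot germinationFraction fraction of seeds that germinate, in [0, 1].
#' @slot seedAxisRange range of seed major axes, pixels.
#' @slot seedAspectRange range of minor/major axis ratios.
#' @slot radicleLengthRange,radicleWidthRange radicle geometry ranges, pixels.
#' @slot debrisDensity expected debris particles per image.
#' @slot backgroundLevel,discLevel,seedLevel,noiseSd grayscale rendering
#'   levels in [0, 1] and additive noise standard deviation.
#' @slot maxPlaceRetries bounded retries when rejecting overlapping seeds.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulateImage}}
#' @name SimConfig-class
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
    representation(imageSize = "integer", filterDiameter = "numeric",
                   nSeeds = "numeric", germinationFraction = "numeric",
                   seedAxisRange = "numeric", seedAspectRange = "numeric",
                   radicleLengthRange = "numeric",
                   radicleWidthRange = "numeric", debrisDensity = "numeric",
                   backgroundLevel = "numeric", discLevel = "numeric",
                   seedLevel = "numeric", noiseSd = "numeric",
                   maxPlaceRetries = "integer"),
    validity = function(object) {
        rng <- function(r) length(r) == 2L && all(r > 0) && r[1] <= r[2]
        if (object@imageSize < 16L) return("imageSize too small")
        if (object@filterDiameter <= 0 ||
            object@filterDiameter > object@imageSize)
            return("filterDiameter must be positive and fit in the image")
        if (object@nSeeds < 0) return("nSeeds must be non-negative")
        if (object@germinationFraction < 0 || object@germinationFraction > 1)
            return("germinationFraction must be in [0, 1]")
        if (!rng(object@seedAxisRange)) return("invalid seedAxisRange")
        if (!rng(object@seedAspectRange) || object@seedAspectRange[2] > 1)
            return("invalid seedAspectRange")
        if (!rng(object@radicleLengthRange)) return("invalid radicleLengthRange")
        if (!rng(object@radicleWidthRange)) return("invalid radicleWidthRange")
        if (object@debrisDensity < 0) return("debrisDensity must be >= 0")
        if (object@noiseSd < 0) return("noiseSd must be >= 0")
        TRUE
    })

#' AssayScene: a simulated assay image with exact ground truth
#'
#' @slot image numeric matrix in [0, 1], rows = y, columns = x.
#' @slot annotation the exact \code{\link{ImageAnnotation}} of the rendered
#'   objects.
#' @slot config the \code{\link{SimConfig}} used.
#' @slot rngSeed the integer seed the scene was rendered with.
#'
#' @seealso \code{\link{simulateImage}}
#' @name AssayScene-class
#' @aliases AssayScene
#' @exportClass AssayScene
setClass("AssayScene",
    representation(image = "matrix", annotation = "ImageAnnotation",
                   config = "SimConfig", rngSeed = "numeric"),
    validity = function(object) {
        if (!is.numeric(object@image)) return("image must be numeric")
        if (nrow(object@image) != object@annotation@height ||
            ncol(object@image) != object@annotation@width)
            return("image dimensions disagree with the annotation")
        TRUE
    })

#' AnchorSet: K prior box shapes at the network input resolution
#'
#' Anchor boxes are the pre-defined bounding-box shapes that parameterize a
#' grid-and-anchor detector's output; here they are derived from annotated
#' training boxes by K-means clustering (default K = 9) under the
#' 1 - IoU distance between center-aligned boxes.
#'
#' @slot anchors numeric matrix with K rows and columns \code{w}, \code{h}
#'   (pixels), sorted by area ascending.
#' @slot inputResolution resolution the anchors refer to (default 608).
#'
#' @seealso \code{\link{kmeansAnchors}}
#' @name AnchorSet-class
#' @aliases AnchorSet
#' @exportClass AnchorSet
setClass("AnchorSet",
    representation(anchors = "matrix", inputResolution = "numeric"),
    validity = function(object) {
        a <- object@anchors
        if (ncol(a) != 2L || nrow(a) < 1L)
            return("anchors must be a K x 2 matrix")
        if (any(a <= 0) || !all(is.finite(a)))
            return("anchor dimensions must be positive and finite")
        areas <- a[, 1] * a[, 2]
        if (is.unsorted(areas)) return("anchors must be sorted by area")
        if (object@inputResolution <= 0)
            return("inputResolution must be positive")
        TRUE
    })

#' Construct an AnchorSet
#'
#' @param wh K x 2 matrix (or 2-column data.frame) of widths and heights in
#'   pixels; rows are re-sorted by area ascending.
#' @param inputResolution network input resolution the shapes refer to.
#' @return An \code{AnchorSet}.
#' @examples
#' anchorSet(cbind(w = c(30, 10), h = c(30, 12)))
#' @export
anchorSet <- function(wh, inputResolution = 608) {
    wh <- as.matrix(wh)
    colnames(wh) <- c("w", "h")
    wh <- wh[order(wh[, 1] * wh[, 2]), , drop = FALSE]
    rownames(wh) <- NULL
    new("AnchorSet", anchors = wh,
        inputResolution = as.numeric(inputResolution))
}

#' TrainingRecipe: detector training hyperparameters as config metadata
#'
#' Records the training recipe of the detector (optimizer, schedule,
#' augmentation, anchors) so it can be serialized alongside results. The
#' defaults are the assay detector's settings: stochastic gradient descent
#' with momentum 0.9, learning rate 1e-3, weight decay 5e-4, 20000 epochs
#' with tenfold learning-rate drops at epochs 16000 and 18000, input
#' resolution 608. Training itself is out of scope here; the recipe is
#' metadata, written and read by \code{\link{writeTrainingRecipe}} and
#' \code{\link{readTrainingRecipe}}.
#'
#' @slot optimizer optimizer name.
#' @slot momentum,learningRate,weightDecay positive rates.
#' @slot maxEpochs total training epochs.
#' @slot lrDropEpochs epochs at which the learning rate is divided by
#'   \code{lrDropFactor}; all strictly below \code{maxEpochs}.
#' @slot lrDropFactor the division factor (default 10).
#' @slot inputResolution square network input resolution.
#' @slot augmentation character vector of augmentation flags.
#' @slot anchors the \code{\link{AnchorSet}} used.
#'
#' @name TrainingRecipe-class
#' @aliases TrainingRecipe
#' @exportClass TrainingRecipe
setClass("TrainingRecipe",
    representation(optimizer = "character", momentum = "numeric",
                   learningRate = "numeric", weightDecay = "numeric",
                   maxEpochs = "integer", lrDropEpochs = "integer",
                   lrDropFactor = "numeric", inputResolution = "integer",
                   augmentation = "character", anchors = "AnchorSet"),
    validity = function(object) {
        if (object@momentum <= 0 || object@learningRate <= 0 ||
            object@weightDecay <= 0)
            return("momentum, learningRate and weightDecay must be positive")
        if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
        if (any(object@lrDropEpochs >= object@maxEpochs))
            return("lrDropEpochs must all be < maxEpochs")
        if (object@lrDropFactor <= 1) return("lrDropFactor must be > 1")
        if (object@inputResolution < 32L)
            return("inputResolution must be >= 32")
        TRUE
    })

#' EvalReport: evaluation of predicted counts against hand counts
#'
#' @slot avgGermDiff mean absolute germination difference, percentage points.
#' @slot perClassDeviation signed per-class deviation (percent; positive =
#'   underestimation), named \code{seed}, \code{radicle}.
#' @slot histogram data.frame (\code{bin}, \code{pct}) of per-image error
#'   ranges; percentages sum to 100.
#' @slot nImages images entering the metric; \code{nExcluded} images dropped
#'   because germination was undefined on either side.
#' @slot operatingPoint list with the model/checkpoint id and objectness
#'   threshold the report refers to.
#' @slot comparison the hand-count vs tool comparison table (see
#'   \code{\link{comparisonTable}}), possibly empty.
#'
#' @name EvalReport-class
#' @aliases EvalReport
#' @exportClass EvalReport
setClass("EvalReport",
    representation(avgGermDiff = "numeric", perClassDeviation = "numeric",
                   histogram = "data.frame", nImages = "integer",
                   nExcluded = "integer", operatingPoint = "list",
                   comparison = "data.frame"),
    validity = function(object) {
        if (object@avgGermDiff < 0) return("avgGermDiff must be >= 0")
        if (object@nImages > 0L && nrow(object@histogram) > 0L &&
            abs(sum(object@histogram$pct) - 100) > 0.01)
            return("histogram percentages must sum to 100 (+/- 0.01)")
        TRUE
    })

#' SweepResult: a grid of operating points and the selected optimum
#'
#' @slot grid data.frame with one row per evaluated setting: \code{setting},
#'   \code{avgGermDiff}, \code{seedDeviation}, \code{radicleDeviation}.
#' @slot selected the setting attaining the minimum \code{avgGermDiff}
#'   (ties broken toward the smallest/earliest setting).
#' @slot what \code{"threshold"} or \code{"checkpoint"}.
#'
#' @seealso \code{\link{sweepThreshold}}, \code{\link{sweepCheckpoints}}
#' @name SweepResult-class
#' @aliases SweepResult
#' @exportClass SweepResult
setClass("SweepResult",
    representation(grid = "data.frame", selected = "ANY", what = "character"),
    validity = function(object) {
        if (nrow(object@grid) < 1L) return("grid must be non-empty")
        i <- match(object@selected, object@grid$setting)
        if (is.na(i)) return("selected setting must be on the grid")
        if (object@grid$avgGermDiff[i] >
            min(object@grid$avgGermDiff) + 1e-12)
            return("selected setting must attain the minimum avgGermDiff")
        TRUE
    })
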