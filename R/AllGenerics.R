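#' Accessors for annotation and scene objects
#'
#' \code{boxes} returns the box table of an annotation (or of a scene's
#' annotation); \code{imageId} the image identifier; \code{imageDim} the
#' \code{c(width, height)} pixel dimensions; \code{nBoxes} the number of
#' boxes, optionally per class; \code{sceneImage} the rendered raster of an
#' \code{\link{AssayScene}}; \code{anchors} the K x 2 anchor matrix of an
#' \code{\link{AnchorSet}}.
#'
#' @param x the object.
#' @param label optional class label to count.
#' @return See the individual descriptions.
#' @examples
#' ann <- imageAnnotation("a", 50, 50,
#'   data.frame(xMin = 0, yMin = 0, xMax = 10, yMax = 10, label = "seed"))
#' boxes(ann); nBoxes(ann); imageDim(ann)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))
#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("imageDim", function(x) standardGeneric("imageDim"))
#' @rdname accessors
#' @export
setGeneric("nBoxes", function(x, label = NULL) standardGeneric("nBoxes"))
#' @rdname accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname accessors
#' @export
setMethod("boxes", "ImageAnnotation", function(x) x@boxes)
#' @rdname accessors
#' @export
setMethod("boxes", "AssayScene", function(x) x@annotation@boxes)
#' @rdname accessors
#' @export
setMethod("imageId", "ImageAnnotation", function(x) x@imageId)
#' @rdname accessors
#' @export
setMethod("imageId", "AssayScene", function(x) x@annotation@imageId)
#' @rdname accessors
#' @export
setMethod("imageDim", "ImageAnnotation",
          function(x) c(width = as.numeric(x@width),
                        height = as.numeric(x@height)))
#' @rdname accessors
#' @export
setMethod("imageDim", "AssayScene", function(x) imageDim(x@annotation))
#' @rdname accessors
#' @export
setMethod("nBoxes", "ImageAnnotation", function(x, label = NULL) {
    if (is.null(label)) nrow(x@boxes) else sum(x@boxes$label == label)
})
#' @rdname accessors
#' @export
setMethod("nBoxes", "AssayScene",
          function(x, label = NULL) nBoxes(x@annotation, label))
#' @rdname accessors
#' @export
setMethod("sceneImage", "AssayScene", function(x) x@image)
#' @rdname accessors
#' @export
setMethod("anchors", "AnchorSet", function(x) x@anchors)
#' @rdname accessors
#' @export
setMethod("anchors", "TrainingRecipe", function(x) x@anchors@anchors)

#' Accessors for annotation objects
#'
#' @param x an \code{ImageAnnotation} or \code{AssayScene}.
#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))
#' @rdname accessors
#' @export
setMethod("annotation", "AssayScene", function(x) x@annotation)

#' Accessors for evaluation objects
#'
#' \code{avgGermDiffValue} returns the mean absolute germination difference
#' of an \code{\link{EvalReport}}; \code{selectedSetting} and
#' \code{sweepGrid} expose a \code{\link{SweepResult}}.
#'
#' @param x the object.
#' @rdname accessors
#' @export
setGeneric("avgGermDiffValue", function(x) standardGeneric("avgGermDiffValue"))
#' @rdname accessors
#' @export
setMethod("avgGermDiffValue", "EvalReport", function(x) x@avgGermDiff)
#' @rdname accessors
#' @export
setGeneric("selectedSetting", function(x) standardGeneric("selectedSetting"))
#' @rdname accessors
#' @export
setMethod("selectedSetting", "SweepResult", function(x) x@selected)
#' @rdname accessors
#' @export
setGeneric("sweepGrid", function(x) standardGeneric("sweepGrid"))
#' @rdname accessors
#' @export
setMethod("sweepGrid", "SweepResult", function(x) x@grid)

setMethod("show", "ImageAnnotation", function(object) {
    cnt <- table(factor(object@boxes$label, levels = classLabels()))
    cat(sprintf("ImageAnnotation '%s' (%d x %d px)\n", object@imageId,
                object@width, object@height))
    cat(sprintf("  %d boxes: %s\n", nrow(object@boxes),
                paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: %d px image, disc %.0f px, ~%.0f seeds, ",
        "germination %.2f, debris %.0f\n"),
        object@imageSize, object@filterDiameter, object@nSeeds,
        object@germinationFraction, object@debrisDensity))
})

setMethod("show", "AssayScene", function(object) {
    cat(sprintf("AssayScene '%s' (%d x %d px, rngSeed %d)\n",
                object@annotation@imageId, object@annotation@width,
                object@annotation@height, as.integer(object@rngSeed)))
    cat(sprintf("  seeds: %d, radicle onsets: %d\n",
                nBoxes(object, "seed"), nBoxes(object, "radicle")))
})

setMethod("show", "AnchorSet", function(object) {
    cat(sprintf("AnchorSet: %d anchors at input resolution %g\n",
                nrow(object@anchors), object@inputResolution))
    print(round(object@anchors, 1))
})

setMethod("show", "TrainingRecipe", function(object) {
    cat(sprintf(paste0(
        "TrainingRecipe: %s, momentum %g, lr %g, decay %g, %d epochs ",
        "(lr/%g at %s), input %d\n"),
        object@optimizer, object@momentum, object@learningRate,
        object@weightDecay, object@maxEpochs, object@lrDropFactor,
        paste(object@lrDropEpochs, collapse = ", "),
        object@inputResolution))
})

setMethod("show", "EvalReport", function(object) {
    cat(sprintf(paste0(
        "EvalReport over %d images (%d excluded):\n",
        "  average germination difference: %.2f percentage points\n"),
        object@nImages, object@nExcluded, object@avgGermDiff))
    if (length(object@perClassDeviation))
        cat(sprintf("  per-class deviation (%% , + = underestimation): %s\n",
                    paste(sprintf("%s %.2f", names(object@perClassDeviation),
                                  object@perClassDeviation),
                          collapse = ", ")))
    if (length(object@operatingPoint))
        cat(sprintf("  operating point: %s\n",
                    paste(sprintf("%s=%s", names(object@operatingPoint),
                                  unlist(object@operatingPoint)),
                          collapse = ", ")))
})

setMethod("show", "SweepResult", function(object) {
    cat(sprintf("SweepResult (%s sweep, %d settings)\n", object@what,
                nrow(object@grid)))
    cat(sprintf("  selected: %s (avg germination difference %.3f)\n",
                format(object@selected),
                object@grid$avgGermDiff[
                    match(object@selected, object@grid$setting)]))
})
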