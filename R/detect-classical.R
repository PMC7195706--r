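#' Parameters of the classical morphological detector
#'
#' Defaults are tied to the simulator defaults (\code{\link{simConfig}}):
#' the opening radius is sized to erase radicles (width <= 6 px) while
#' preserving seed bodies (minor axes >= 15 px), and the area band brackets
#' the ellipse areas implied by the default seed axis ranges.
#'
#' @param discThreshold gray level separating disc from surround;
#'   \code{NULL} = automatic (Otsu).
#' @param seedThreshold gray level separating dark objects from the disc;
#'   \code{NULL} = automatic (Otsu within the disc).
#' @param openRadius structuring-element radius (px) of the opening that
#'   separates seed bodies from thin structures.
#' @param seedAreaRange accepted component area band (px^2) for seeds.
#' @param seedEccMax maximum eccentricity accepted for a seed component.
#' @param minRadicleArea minimum residual thin-component area (px^2)
#'   accepted as a radicle.
#' @return A named list of parameters.
#' @export
classicalParams <- function(discThreshold = NULL, seedThreshold = NULL,
                            openRadius = 4L, seedAreaRange = c(140, 1700),
                            seedEccMax = 0.95, minRadicleArea = 35) {
    list(discThreshold = discThreshold, seedThreshold = seedThreshold,
         openRadius = as.integer(openRadius),
         seedAreaRange = as.numeric(seedAreaRange),
         seedEccMax = as.numeric(seedEccMax),
         minRadicleArea = as.numeric(minRadicleArea))
}

.toGray <- function(image) {
    if (is(image, "AssayScene")) return(image@image)
    if (length(dim(image)) == 3L) {
        # RGB array (rows, cols, channels) -> luminance
        return(0.299 * image[, , 1] + 0.587 * image[, , 2] +
               0.114 * image[, , 3])
    }
    image
}

# per-label bounding boxes (internal 0-based half-open) and pixel counts
.labelBoxes <- function(L, nLabels) {
    idx <- which(L > 0)
    if (length(idx) == 0L)
        return(data.frame(label = integer(0), xMin = numeric(0),
                          yMin = numeric(0), xMax = numeric(0),
                          yMax = numeric(0), area = numeric(0)))
    nr <- nrow(L)
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    lab <- L[idx]
    f <- factor(lab, levels = seq_len(nLabels))
    data.frame(label = seq_len(nLabels),
               xMin = tapply(cc, f, min) - 1,
               yMin = tapply(r, f, min) - 1,
               xMax = as.numeric(tapply(cc, f, max)),
               yMax = as.numeric(tapply(r, f, max)),
               area = as.numeric(table(f)))
}

#' Classical reference detector for filter-assay images
#'
#' A fully classical back-end that makes the whole pipeline runnable and
#' testable without a trained network. Seeds are found by thresholding dark
#' objects inside the bright filter disc, a morphological opening that
#' erases thin structures, connected-component labelling, and filtering by
#' area and eccentricity bounds. Radicle onsets are found as thin elongated
#' residuals (threshold minus opened image) of sufficient size attached to
#' a detected seed; at most one onset is reported per qualifying seed, with
#' its box centered on the seed-radicle junction and sized by the seed's
#' minor axis.
#'
#' Each detection carries a pseudo-objectness in [0.01, 0.99] derived from
#' the margins of its shape scores (how comfortably the component sits
#' inside the area/eccentricity bands; contact size for radicles), so
#' objectness-threshold sweeps are exercisable against this back-end.
#'
#' @param image numeric matrix in [0, 1] (rows = y), an RGB array, or an
#'   \code{\link{AssayScene}}.
#' @param params see \code{\link{classicalParams}}.
#' @return A detection data.frame (see \code{\link{detectionTable}}).
#' @export
detectClassical <- function(image, params = classicalParams()) {
    img <- .toGray(image)
    if (length(img) == 0L || diff(range(img)) < 1e-6)
        return(.emptyDetections())

    # Otsu on a strided subsample: the threshold estimate is unchanged and
    # the histogram cost stays flat in the image size
    sub <- function(v) {
        if (length(v) > 250000L) v <- v[seq(1L, length(v), by = 7L)]
        matrix(v, ncol = 1L)
    }
    thDisc <- params$discThreshold
    if (is.null(thDisc))
        thDisc <- EBImage::otsu(EBImage::Image(sub(as.vector(img))),
                                range = c(0, 1))
    discMask <- img > thDisc
    if (sum(discMask) < 0.01 * length(img))
        return(.emptyDetections())
    discMask <- EBImage::fillHull(discMask)
    Ld <- EBImage::bwlabel(discMask)
    tab <- tabulate(Ld[Ld > 0])
    discMask <- Ld == which.max(tab)
    discMask <- EBImage::erode(discMask, EBImage::makeBrush(7, "disc"))

    inDisc <- img[discMask]
    thSeed <- params$seedThreshold
    if (is.null(thSeed)) {
        thSeed <- EBImage::otsu(EBImage::Image(sub(inDisc)),
                                range = c(0, 1))
    }
    binary <- (img < thSeed) & discMask
    if (!any(binary)) return(.emptyDetections())

    brush <- EBImage::makeBrush(2L * params$openRadius + 1L, "disc")
    opened <- EBImage::opening(binary, brush)
    L <- EBImage::bwlabel(opened)
    nL <- max(L)
    if (nL == 0L) return(.emptyDetections())

    bb <- .labelBoxes(L, nL)
    mom <- EBImage::computeFeatures.moment(L)
    ecc <- mom[, "m.eccentricity"]
    minor <- mom[, "m.majoraxis"] * sqrt(1 - pmin(ecc, 0.999)^2)
    aLo <- params$seedAreaRange[1]; aHi <- params$seedAreaRange[2]
    isSeed <- bb$area >= aLo & bb$area <= aHi & ecc <= params$seedEccMax
    if (!any(isSeed)) return(.emptyDetections())

    # pseudo-objectness: normalized margin from the area band edges and
    # the eccentricity bound
    areaScore <- pmin(bb$area - aLo, aHi - bb$area) / ((aHi - aLo) / 2)
    eccScore <- (params$seedEccMax - ecc) / params$seedEccMax
    seedObj <- pmin(pmax(0.25 + 0.6 * areaScore + 0.8 * eccScore, 0.01), 0.99)

    seedLabels <- bb$label[isSeed]
    seedBoxes <- data.frame(xMin = bb$xMin[isSeed], yMin = bb$yMin[isSeed],
                            xMax = bb$xMax[isSeed], yMax = bb$yMax[isSeed],
                            label = "seed", stringsAsFactors = FALSE)
    dets <- detectionTable(seedBoxes, seedObj[isSeed])

    # --- radicle onsets: thin residuals attached to seeds ---
    thin <- binary & !EBImage::dilate(opened, EBImage::makeBrush(3, "disc"))
    if (any(thin)) {
        Lt <- EBImage::bwlabel(thin)
        tArea <- tabulate(Lt[Lt > 0])
        qual <- which(tArea >= params$minRadicleArea)
        if (length(qual)) {
            thinQ <- matrix(Lt %in% qual, nrow(Lt), ncol(Lt))
            # propagate thin labels outward so contact with seed bodies is
            # detectable on the seed side
            Ltd <- EBImage::dilate(Lt * thinQ, EBImage::makeBrush(7, "disc"))
            contactIdx <- which(Ltd > 0 & L > 0)
            if (length(contactIdx)) {
                seedAt <- L[contactIdx]
                keep <- seedAt %in% seedLabels
                contactIdx <- contactIdx[keep]; seedAt <- seedAt[keep]
                if (length(contactIdx)) {
                    nr <- nrow(L)
                    r <- ((contactIdx - 1L) %% nr) + 1L
                    cc <- ((contactIdx - 1L) %/% nr) + 1L
                    f <- factor(seedAt)
                    jy <- tapply(r, f, mean); jx <- tapply(cc, f, mean)
                    contact <- as.numeric(table(f))
                    lab <- as.integer(levels(f))
                    side <- minor[lab]
                    thinLab <- tapply(Ltd[contactIdx], f,
                                      function(v) v[1])
                    radObj <- pmin(pmax(
                        0.30 + 0.10 * sqrt(contact) +
                            0.002 * tArea[thinLab], 0.01), 0.99)
                    radBoxes <- data.frame(
                        xMin = jx - side / 2, yMin = jy - side / 2,
                        xMax = jx + side / 2, yMax = jy + side / 2,
                        label = "radicle", stringsAsFactors = FALSE)
                    radBoxes$xMin <- pmax(radBoxes$xMin, 0)
                    radBoxes$yMin <- pmax(radBoxes$yMin, 0)
                    radBoxes$xMax <- pmin(radBoxes$xMax, ncol(L))
                    radBoxes$yMax <- pmin(radBoxes$yMax, nrow(L))
                    dets <- rbind(dets,
                                  detectionTable(radBoxes, radObj))
                }
            }
        }
    }
    rownames(dets) <- NULL
    dets
}
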