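#' Count seeds and radicle onsets in one image's detections
#'
#' Produces the per-image record of the results table: total seeds, number
#' of radicle onsets (each marking one germinated seed), and the derived
#' germination percentage. The two classes are counted independently —
#' radicle detections are not matched one-to-one to seed detections.
#'
#' @param sample sample name (the input image's name).
#' @param dets post-NMS detection data.frame.
#' @return One-row data.frame: \code{sample}, \code{totalSeeds},
#'   \code{germinatedSeeds}, \code{germinationPct} (NA when no seeds were
#'   detected).
#' @examples
#' d <- detectionTable(data.frame(xMin = c(0, 20), yMin = c(0, 20),
#'                                xMax = c(10, 30), yMax = c(10, 30),
#'                                label = c("seed", "radicle")),
#'                     c(0.9, 0.8))
#' countImage("img1", d)
#' @export
countImage <- function(sample, dets) {
    ns <- sum(dets$class == "seed")
    nr <- sum(dets$class == "radicle")
    data.frame(sample = as.character(sample), totalSeeds = ns,
               germinatedSeeds = nr,
               germinationPct = suppressWarnings(germinationPct(ns, nr)),
               stringsAsFactors = FALSE)
}

#' Write the four-column results table
#'
#' The tool's tabular deliverable: a comma-separated UTF-8 file with header
#' \code{sample, total_seeds, germinated_seeds, germination_pct}, one row
#' per image in input order, percentages rendered with two decimals and
#' undefined values as the literal \code{NA}.
#'
#' @param results data.frame of stacked \code{\link{countImage}} rows.
#' @param path destination file; written atomically (temp file + rename).
#' @return Invisibly, the rendered lines.
#' @export
writeCountsTable <- function(results, path) {
    if (anyDuplicated(results$sample))
        warning("duplicate sample names in results table", call. = FALSE)
    pct <- ifelse(is.na(results$germinationPct), "NA",
                  sprintf("%.2f", results$germinationPct))
    lines <- c("sample,total_seeds,germinated_seeds,germination_pct",
               sprintf("%s,%d,%d,%s", results$sample, results$totalSeeds,
                       results$germinatedSeeds, pct))
    tmp <- paste0(path, ".tmp")
    con <- file(tmp, open = "w", encoding = "UTF-8")
    writeLines(lines, con)
    close(con)
    file.rename(tmp, path)
    invisible(lines)
}

#' Read a results or ground-truth counts table
#'
#' @param path a CSV written by \code{\link{writeCountsTable}} (or a
#'   hand-count table with the same four columns).
#' @return data.frame with columns \code{sample}, \code{totalSeeds},
#'   \code{germinatedSeeds}, \code{germinationPct}.
#' @export
readCountsTable <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(d) <- c("sample", "totalSeeds", "germinatedSeeds",
                  "germinationPct")[seq_along(names(d))]
    d
}

.classColors <- c(seed = "#800080",     # purple
                  radicle = "#00FF00",  # bright green
                  haustorium = "#B22222")

#' Render a detection overlay on an assay image
#'
#' Draws one rectangle per detection onto an RGB copy of the image: seeds
#' in purple, radicle onsets in bright green, haustoria (if present) in
#' dark red. The output raster keeps the input's pixel dimensions exactly;
#' boxes reaching outside the image are clipped with a warning.
#'
#' @param image numeric matrix in [0, 1] or an \code{\link{AssayScene}}.
#' @param dets detection data.frame (or a box data.frame with labels).
#' @param lineWidth rectangle border thickness in pixels.
#' @return RGB array of dim \code{c(rows, cols, 3)}.
#' @export
renderOverlay <- function(image, dets, lineWidth = 3L) {
    img <- .toGray(image)
    h <- nrow(img); w <- ncol(img)
    rgb <- array(img, dim = c(h, w, 3))
    cls <- if (!is.null(dets$class)) dets$class else dets$label
    if (length(cls) && any(dets$xMin < 0 | dets$yMin < 0 |
                           dets$xMax > w | dets$yMax > h))
        warning("box(es) outside the image were clipped", call. = FALSE)
    for (i in seq_len(nrow(dets))) {
        col <- grDevices::col2rgb(.classColors[[cls[i]]])[, 1] / 255
        x0 <- max(1L, floor(dets$xMin[i]) + 1L)
        y0 <- max(1L, floor(dets$yMin[i]) + 1L)
        x1 <- min(w, ceiling(dets$xMax[i]))
        y1 <- min(h, ceiling(dets$yMax[i]))
        if (x1 <= x0 || y1 <= y0) next
        t <- seq_len(lineWidth) - 1L
        for (ch in 1:3) {
            rgb[pmin(y0 + t, h), x0:x1, ch] <- col[ch]
            rgb[pmax(y1 - t, 1L), x0:x1, ch] <- col[ch]
            rgb[y0:y1, pmin(x0 + t, w), ch] <- col[ch]
            rgb[y0:y1, pmax(x1 - t, 1L), ch] <- col[ch]
        }
    }
    rgb
}

#' Summary arithmetic of the extended (segmentation) system
#'
#' The extended three-class system counts objects and class pixels and
#' derives rates and mean individual object sizes: germination rate =
#' germinated / seeds, haustoria development rate = haustoria / germinated,
#' and mean size per class = class pixels / class objects x pixel area.
#' Reported rates are rounded to two decimals; mean sizes keep the same
#' reporting precision. The summary is homogeneous of degree one in
#' \code{pixelArea}.
#'
#' @param nSeeds,nGerminated,nHaustoria object counts.
#' @param classPixelCounts numeric vector of pixels per class, in order
#'   (seed, radicle, haustorium).
#' @param pixelArea mm^2 per pixel (> 0).
#' @return list with \code{germinationRate}, \code{haustoriaRate},
#'   \code{meanSize} (named mm^2 per class, NA for absent classes), plus the
#'   inputs.
#' @examples
#' s <- segmentationSummary(6, 3, 2, c(400, 300, 100), 0.1)
#' s$germinationRate  # 0.50
#' s$meanSize         # 6.67 10 5
#' @export
segmentationSummary <- function(nSeeds, nGerminated, nHaustoria,
                                classPixelCounts, pixelArea) {
    if (any(c(nSeeds, nGerminated, nHaustoria) < 0))
        stop("counts must be non-negative", call. = FALSE)
    if (pixelArea <= 0) stop("pixelArea must be positive", call. = FALSE)
    stopifnot(length(classPixelCounts) == 3L)
    objects <- c(seed = nSeeds, radicle = nGerminated,
                 haustorium = nHaustoria)
    if (any(objects == 0 & classPixelCounts > 0))
        stop("class with zero objects but nonzero pixels: inconsistent input",
             call. = FALSE)
    meanSize <- ifelse(objects > 0,
                       round(classPixelCounts / objects * pixelArea, 2),
                       NA_real_)
    names(meanSize) <- names(objects)
    list(nSeeds = nSeeds, nGerminated = nGerminated,
         nHaustoria = nHaustoria,
         classPixelCounts = classPixelCounts, pixelArea = pixelArea,
         germinationRate = if (nSeeds > 0)
             round(nGerminated / nSeeds, 2) else NA_real_,
         haustoriaRate = if (nGerminated > 0)
             round(nHaustoria / nGerminated, 2) else NA_real_,
         meanSize = meanSize)
}
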