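#' Parse a Pascal-VOC (LabelImg) annotation document
#'
#' Reads the XML dialect written by the LabelImg annotation tool: a
#' \code{<size>} block with image dimensions and one \code{<object>} block
#' per box, each with a \code{<name>} and a \code{<bndbox>}. VOC coordinates
#' are 1-based inclusive pixel indices; they are converted to the internal
#' 0-based, half-open convention via \code{xMin = xmin - 1, xMax = xmax}
#' (and likewise for y), so a VOC box (1, 1, 10, 10) becomes
#' \eqn{[0, 10) \times [0, 10)}.
#'
#' Class names are matched case-insensitively against
#' \code{\link{classLabels}}; an unknown name, a malformed document, or a
#' box extending outside the image raises an error identifying the culprit.
#'
#' @param xml path to an XML file, a literal XML string, or an
#'   \code{xml2::xml_document}.
#' @return An \code{\link{ImageAnnotation}}.
#' @seealso \code{\link{writeVoc}}, \code{\link{parseDarknetTxt}}
#' @export
parseVoc <- function(xml) {
    doc <- if (inherits(xml, "xml_document")) xml else
        tryCatch(xml2::read_xml(xml),
                 error = function(e) stop("malformed XML: ",
                                          conditionMessage(e), call. = FALSE))
    need <- function(node, what) {
        child <- xml2::xml_find_first(node, what)
        if (inherits(child, "xml_missing"))
            stop(sprintf("malformed VOC document: missing <%s> element", what),
                 call. = FALSE)
        child
    }
    numChild <- function(node, what) {
        v <- suppressWarnings(as.numeric(xml2::xml_text(need(node, what))))
        if (is.na(v))
            stop(sprintf("malformed VOC document: non-numeric <%s>", what),
                 call. = FALSE)
        v
    }
    sz <- need(doc, "size")
    width <- numChild(sz, "width")
    height <- numChild(sz, "height")
    imageId <- xml2::xml_text(xml2::xml_find_first(doc, "filename"))
    if (is.na(imageId)) imageId <- ""
    imageId <- sub("\\.[A-Za-z0-9]+$", "", imageId)

    objs <- xml2::xml_find_all(doc, "object")
    if (length(objs) == 0L)
        return(imageAnnotation(imageId, width, height))
    rows <- lapply(seq_along(objs), function(i) {
        ob <- objs[[i]]
        nm <- tolower(trimws(xml2::xml_text(need(ob, "name"))))
        if (!nm %in% classLabels())
            stop(sprintf("unknown class name '%s' in object %d (accepted: %s)",
                         nm, i, paste(classLabels(), collapse = ", ")),
                 call. = FALSE)
        bb <- need(ob, "bndbox")
        xmin <- numChild(bb, "xmin"); ymin <- numChild(bb, "ymin")
        xmax <- numChild(bb, "xmax"); ymax <- numChild(bb, "ymax")
        data.frame(xMin = xmin - 1, yMin = ymin - 1, xMax = xmax,
                   yMax = ymax, label = nm, stringsAsFactors = FALSE)
    })
    bx <- do.call(rbind, rows)
    out <- bx$xMin < 0 | bx$yMin < 0 | bx$xMax > width | bx$yMax > height
    if (any(out))
        stop(sprintf("box %d lies outside the %g x %g image",
                     which(out)[1L], width, height), call. = FALSE)
    imageAnnotation(imageId, width, height, bx)
}

#' Write an annotation as a Pascal-VOC (LabelImg) document
#'
#' Inverse of \code{\link{parseVoc}}: internal 0-based half-open boxes are
#' written back as 1-based inclusive VOC integers
#' (\code{xmin = xMin + 1, xmax = xMax}), so
#' \code{parseVoc(writeVoc(a))} reproduces \code{a} exactly for
#' integer-coordinate annotations. Labels are written lower-case.
#'
#' @param annotation an \code{\link{ImageAnnotation}}.
#' @param path optional file path; when omitted the document is returned.
#' @return An \code{xml2::xml_document} (invisibly when \code{path} is given).
#' @export
writeVoc <- function(annotation, path = NULL) {
    stopifnot(is(annotation, "ImageAnnotation"))
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename",
                        paste0(annotation@imageId, ".png"))
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", as.character(annotation@width))
    xml2::xml_add_child(sz, "height", as.character(annotation@height))
    xml2::xml_add_child(sz, "depth", "3")
    bx <- annotation@boxes
    for (i in seq_len(nrow(bx))) {
        ob <- xml2::xml_add_child(doc, "object")
        xml2::xml_add_child(ob, "name", tolower(bx$label[i]))
        bb <- xml2::xml_add_child(ob, "bndbox")
        fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
        xml2::xml_add_child(bb, "xmin", fmt(bx$xMin[i] + 1))
        xml2::xml_add_child(bb, "ymin", fmt(bx$yMin[i] + 1))
        xml2::xml_add_child(bb, "xmax", fmt(bx$xMax[i]))
        xml2::xml_add_child(bb, "ymax", fmt(bx$yMax[i]))
    }
    if (!is.null(path)) {
        xml2::write_xml(doc, path)
        return(invisible(doc))
    }
    doc
}

#' Parse Darknet-style normalized annotation text
#'
#' Each line is \code{class_index center_x center_y box_w box_h} with the
#' four geometric values normalized to [0, 1] relative to the image size.
#' Class indices follow \code{\link{classLabels}} order (0 = seed,
#' 1 = radicle, 2 = haustorium).
#'
#' @param lines character vector of lines, or a path to a .txt file.
#' @param width,height image dimensions in pixels used to de-normalize.
#' @param imageId identifier for the resulting annotation.
#' @return An \code{\link{ImageAnnotation}}.
#' @seealso \code{\link{writeDarknetTxt}}
#' @export
parseDarknetTxt <- function(lines, width, height, imageId = "") {
    if (length(lines) == 1L && !grepl("[\n ]", lines) && file.exists(lines))
        lines <- readLines(lines)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        return(imageAnnotation(imageId, width, height))
    rows <- lapply(seq_along(lines), function(i) {
        f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                  "[[:space:]]+")[[1]]))
        if (length(f) != 5L || anyNA(f))
            stop(sprintf("line %d: expected 'class cx cy w h'", i),
                 call. = FALSE)
        cls <- f[1]
        if (cls != round(cls) || cls < 0 || cls >= length(classLabels()))
            stop(sprintf("line %d: unknown class index %g", i, cls),
                 call. = FALSE)
        if (any(f[2:5] < 0) || any(f[2:5] > 1))
            stop(sprintf("line %d: normalized value outside [0, 1]", i),
                 call. = FALSE)
        cx <- f[2] * width; cy <- f[3] * height
        w <- f[4] * width; h <- f[5] * height
        data.frame(xMin = cx - w / 2, yMin = cy - h / 2,
                   xMax = cx + w / 2, yMax = cy + h / 2,
                   label = classLabels()[cls + 1L], stringsAsFactors = FALSE)
    })
    bx <- do.call(rbind, rows)
    # normalized boxes may touch the border exactly; clip float fuzz
    bx$xMin <- pmax(bx$xMin, 0); bx$yMin <- pmax(bx$yMin, 0)
    bx$xMax <- pmin(bx$xMax, width); bx$yMax <- pmin(bx$yMax, height)
    imageAnnotation(imageId, width, height, bx)
}

#' Write an annotation as Darknet-style normalized text
#'
#' @param annotation an \code{\link{ImageAnnotation}}.
#' @param path optional file path; when omitted the lines are returned.
#' @param digits decimal digits for the normalized values (default 6, which
#'   keeps the parse-write round trip within one pixel on assay-sized
#'   images).
#' @return Character vector of lines (invisibly when \code{path} is given).
#' @export
writeDarknetTxt <- function(annotation, path = NULL, digits = 6L) {
    stopifnot(is(annotation, "ImageAnnotation"))
    bx <- annotation@boxes
    w <- annotation@width; h <- annotation@height
    lines <- if (nrow(bx) == 0L) character(0) else
        sprintf(paste0("%d %.", digits, "f %.", digits, "f %.", digits,
                       "f %.", digits, "f"),
                match(bx$label, classLabels()) - 1L,
                (bx$xMin + bx$xMax) / 2 / w, (bx$yMin + bx$yMax) / 2 / h,
                (bx$xMax - bx$xMin) / w, (bx$yMax - bx$yMin) / h)
    if (!is.null(path)) {
        writeLines(lines, path)
        return(invisible(lines))
    }
    lines
}

#' Germination percentage from seed and radicle-onset counts
#'
#' The assay's key readout: \code{100 * nRadicles / nSeeds}, the percentage
#' of germinated seeds on one filter, where each radicle onset marks one
#' germinated seed. Undefined (\code{NA}) when no seeds were counted.
#' Because the two classes are counted independently, more radicle than seed
#' detections is possible; such values exceed 100 and are returned as
#' computed, with a warning rather than clamping.
#'
#' @param nSeeds,nRadicles non-negative integer counts (vectorized).
#' @return Numeric percentage(s); \code{NA} where \code{nSeeds == 0}.
#' @examples
#' germinationPct(6, 3)   # 50
#' germinationPct(50, 20) # 40
#' germinationPct(0, 0)   # NA
#' @export
germinationPct <- function(nSeeds, nRadicles) {
    if (any(nSeeds < 0) || any(nRadicles < 0))
        stop("counts must be non-negative", call. = FALSE)
    pct <- ifelse(nSeeds > 0, 100 * nRadicles / nSeeds, NA_real_)
    if (any(!is.na(pct) & pct > 100))
        warning("more radicle onsets than seeds: germination percentage ",
                "exceeds 100 (reported unclamped)", call. = FALSE)
    pct
}

#' Hand-count ground-truth table
#'
#' Builds the per-sample reference table of hand-counted seeds and radicle
#' onsets with the derived germination percentage, the form in which
#' validation and test references are kept.
#'
#' @param sample character sample names (typically image stems).
#' @param nSeeds,nRadicles non-negative counts.
#' @return data.frame with columns \code{sample}, \code{nSeeds},
#'   \code{nRadicles}, \code{germinationPct}.
#' @export
groundTruthCounts <- function(sample, nSeeds, nRadicles) {
    stopifnot(length(sample) == length(nSeeds),
              length(sample) == length(nRadicles))
    data.frame(sample = as.character(sample),
               nSeeds = as.integer(nSeeds),
               nRadicles = as.integer(nRadicles),
               germinationPct = suppressWarnings(
                   germinationPct(nSeeds, nRadicles)),
               stringsAsFactors = FALSE)
}
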