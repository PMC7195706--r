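vocDoc <- function(objects, width = 200, height = 200) {
    obj <- paste(vapply(objects, function(o) sprintf(
        "<object><name>%s</name><bndbox><xmin>%s</xmin><ymin>%s</ymin><xmax>%s</xmax><ymax>%s</ymax></bndbox></object>",
        o[[1]], o[[2]], o[[3]], o[[4]], o[[5]]), character(1)),
        collapse = "")
    sprintf(paste0(
        "<annotation><filename>img.png</filename>",
        "<size><width>%d</width><height>%d</height><depth>3</depth></size>",
        "%s</annotation>"), width, height, obj)
}

test_that("VOC parsing converts 1-based inclusive indices to the internal convention", {
    ann <- parseVoc(vocDoc(list(list("seed", 11, 11, 40, 35),
                                list("seed", 101, 101, 130, 128))))
    expect_equal(nBoxes(ann, "seed"), 2)
    expect_equal(nBoxes(ann, "radicle"), 0)
    expect_equal(boxes(ann)$xMin, c(10, 100))
    expect_equal(boxes(ann)$xMax, c(40, 130))
    expect_equal(boxes(ann)$yMin, c(10, 100))
    expect_equal(boxes(ann)$yMax, c(35, 128))

    mixed <- parseVoc(vocDoc(list(list("seed", 1, 1, 10, 10),
                                  list("Radicle", 50, 50, 60, 60))))
    expect_equal(nBoxes(mixed, "seed"), 1)   # case-insensitive labels
    expect_equal(nBoxes(mixed, "radicle"), 1)

    empty <- parseVoc(vocDoc(list()))
    expect_equal(nBoxes(empty), 0)
    expect_equal(unname(imageDim(empty)), c(200, 200))
})

test_that("VOC parsing rejects malformed input with informative errors", {
    expect_error(parseVoc("<annotation><object/></annotation>"),
                 "size")
    expect_error(parseVoc(vocDoc(list(list("weed", 1, 1, 10, 10)))),
                 "unknown class name 'weed'")
    expect_error(parseVoc(vocDoc(list(list("seed", 1, 1, 500, 10)))),
                 "box 1 lies outside")
    expect_error(parseVoc("<annotation><size><width>x</width>"),
                 "malformed")
})

test_that("VOC write/parse round trip is exact for integer annotations", {
    ann <- imageAnnotation("img", 300, 250, data.frame(
        xMin = c(10, 100, 40), yMin = c(10, 100, 7),
        xMax = c(40, 130, 66), yMax = c(35, 128, 31),
        label = c("seed", "radicle", "haustorium")))
    back <- parseVoc(writeVoc(ann))
    expect_equal(boxes(back), boxes(ann))
    expect_equal(unname(imageDim(back)), c(300, 250))

    emptyBack <- parseVoc(writeVoc(imageAnnotation("e", 50, 60)))
    expect_equal(nBoxes(emptyBack), 0)

    f <- withr::local_tempfile(fileext = ".xml")
    writeVoc(ann, f)
    expect_equal(boxes(parseVoc(f)), boxes(ann))
})

test_that("Darknet text converts normalized center/size to pixel boxes", {
    ann <- parseDarknetTxt("0 0.5 0.5 0.1 0.1", 1000, 1000)
    expect_equal(as.numeric(boxes(ann)[1, 1:4]), c(450, 450, 550, 550))
    expect_equal(boxes(ann)$label, "seed")

    expect_equal(nBoxes(parseDarknetTxt(character(0), 100, 100)), 0)
    expect_error(parseDarknetTxt("0 1.5 0.5 0.1 0.1", 100, 100),
                 "line 1.*outside")
    expect_error(parseDarknetTxt(c("0 0.5 0.5 0.1 0.1", "7 0.5 0.5 0.1 0.1"),
                                 100, 100),
                 "line 2.*class index")
})

test_that("Darknet round trip preserves boxes within one pixel", {
    withr::with_seed(11, {
        n <- 10
        cx <- runif(n, 100, 2400); cy <- runif(n, 100, 2400)
        w <- runif(n, 10, 120); h <- runif(n, 10, 120)
        ann <- imageAnnotation("rt", 2500, 2500, data.frame(
            xMin = cx - w / 2, yMin = cy - h / 2,
            xMax = cx + w / 2, yMax = cy + h / 2,
            label = sample(classLabels(), n, replace = TRUE)))
    })
    back <- parseDarknetTxt(writeDarknetTxt(ann), 2500, 2500)
    for (col in c("xMin", "yMin", "xMax", "yMax"))
        expect_lt(max(abs(boxes(back)[[col]] - boxes(ann)[[col]])), 1)
    expect_equal(boxes(back)$label, boxes(ann)$label)

    # second pass through the hub convention is idempotent
    again <- parseDarknetTxt(writeDarknetTxt(back), 2500, 2500)
    expect_equal(boxes(again)[1:4], boxes(back)[1:4], tolerance = 1e-6)
})

test_that("cross-dialect conversion through the internal type is stable", {
    ann <- parseDarknetTxt(c("0 0.2 0.2 0.08 0.06", "1 0.6 0.7 0.02 0.02"),
                           1000, 800, imageId = "x")
    viaVoc <- parseVoc(writeVoc(ann))
    expect_equal(nrow(boxes(viaVoc)), 2)
    expect_equal(boxes(viaVoc)$label, boxes(ann)$label)
    expect_true(all(abs(as.matrix(boxes(viaVoc)[1:4]) -
                        as.matrix(boxes(ann)[1:4])) <= 1))
})

test_that("germination percentage follows the assay definition", {
    expect_equal(germinationPct(6, 3), 50)
    expect_equal(germinationPct(50, 20), 40)
    expect_true(is.na(germinationPct(0, 0)))
    expect_error(germinationPct(-1, 0), "non-negative")
    expect_warning(p <- germinationPct(3, 5), "exceeds 100")
    expect_equal(p, 500 / 3)

    # scale-free: multiplying both counts leaves the percentage unchanged
    for (k in c(2, 5, 17))
        expect_equal(germinationPct(6 * k, 3 * k), 50)
})

test_that("ground-truth tables derive the percentage and handle zero seeds", {
    g <- groundTruthCounts(c("a", "b"), c(50, 0), c(20, 0))
    expect_equal(g$germinationPct, c(40, NA))
    expect_error(imageAnnotation("bad", 100, 100, data.frame(
        xMin = 5, yMin = 5, xMax = 5, yMax = 10, label = "seed")))
    expect_error(imageAnnotation("bad", 100, 100, data.frame(
        xMin = 5, yMin = 5, xMax = 120, yMax = 10, label = "seed")))
})
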