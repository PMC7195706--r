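test_that("iou matches hand arithmetic and is a bounded symmetric score", {
    expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
    expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0)
    expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)

    withr::with_seed(3, {
        for (k in 1:50) {
            a <- c(runif(1, 0, 5), runif(1, 0, 5))
            a <- c(a, a + runif(2, 0.1, 4))[c(1, 2, 3, 4)]
            b <- c(runif(1, 0, 5), runif(1, 0, 5))
            b <- c(b, b + runif(2, 0.1, 4))[c(1, 2, 3, 4)]
            v <- iou(a, b)
            expect_gte(v, 0); expect_lte(v, 1)
            expect_equal(v, iou(b, a))
            if (v == 1) expect_equal(a, b)
        }
    })
})

test_that("iouMatrix agrees with the scalar iou", {
    withr::with_seed(4, {
        a <- data.frame(xMin = runif(5), yMin = runif(5))
        a$xMax <- a$xMin + runif(5, 0.2, 2)
        a$yMax <- a$yMin + runif(5, 0.2, 2)
        b <- data.frame(xMin = runif(4), yMin = runif(4))
        b$xMax <- b$xMin + runif(4, 0.2, 2)
        b$yMax <- b$yMin + runif(4, 0.2, 2)
    })
    M <- iouMatrix(a, b)
    for (i in 1:5) for (j in 1:4)
        expect_equal(M[i, j], iou(a[i, ], b[j, ]))
})

test_that("anchor K-means recovers trivial and two-cluster structure", {
    same <- data.frame(xMin = rep(0, 20), yMin = 0, xMax = 24, yMax = 17,
                       label = "seed")
    expect_error(kmeansAnchors(same, K = 2), "distinct")
    # slightly perturb so dedup keeps one shape per box
    one <- kmeansAnchors(cbind(rep(24, 20), rep(17, 20) + 0), K = 1)
    expect_equal(unname(anchors(one)[1, ]), c(24, 17))

    two <- kmeansAnchors(rbind(cbind(rep(20, 10), rep(20, 10)),
                               cbind(rep(100, 10), rep(100, 10))),
                         K = 2, rngSeed = 5)
    expect_equal(unname(anchors(two)), rbind(c(20, 20), c(100, 100)))

    nine <- matrix(c(10, 13, 16, 30, 33, 23, 30, 61, 62,
                     45, 59, 119, 116, 90, 156, 198, 373, 326),
                   ncol = 2)
    fix <- kmeansAnchors(nine, K = 9, rngSeed = 2)
    expect_equal(nrow(anchors(fix)), 9)
    # each shape its own cluster: zero residual objective
    expect_lt(tail(attr(fix, "objective"), 1), 1e-12)
})

test_that("anchor K-means objective is non-increasing over iterations", {
    withr::with_seed(9, {
        wh <- cbind(runif(200, 5, 120), runif(200, 5, 120))
    })
    for (s in 1:5) {
        a <- kmeansAnchors(wh, K = 5, rngSeed = s)
        obj <- attr(a, "objective")
        expect_true(all(diff(obj) <= 1e-12))
        areas <- anchors(a)[, 1] * anchors(a)[, 2]
        expect_false(is.unsorted(areas))
    }
    # deterministic given the seed
    expect_equal(anchors(kmeansAnchors(wh, K = 5, rngSeed = 3)),
                 anchors(kmeansAnchors(wh, K = 5, rngSeed = 3)))
})

test_that("raw grid decoding follows the closed-form parameterization", {
    S <- 19L; A <- 3L
    aset <- anchorSet(cbind(w = c(10, 30, 60), h = c(14, 28, 55)))
    raw <- array(0, dim = c(S, S, A, 7))
    dets <- decodeRaw(raw, aset, 608)
    expect_equal(nrow(dets), S * S * A)       # no filtering in the decoder
    expect_true(all(dets$objectness == 0.5))  # sigma(0) = 0.5
    # first detection: cell (1,1), anchor (10,14), centered at cell center
    expect_equal(as.numeric(dets[1, c("xMax", "xMin")]),
                 c(16 + 5, 16 - 5))
    expect_equal(dets$yMax[1] - dets$yMin[1], 14)

    raw2 <- array(0, dim = c(S, S, A, 7))
    raw2[3, 5, 1, 1] <- 0.4055; raw2[3, 5, 1, 2] <- 0.4055
    raw2[3, 5, 1, 3] <- log(2)
    d2 <- decodeRaw(raw2, aset, 608)
    k <- (3 - 1) * S * A + (5 - 1) * A + 1     # cell-major position
    stride <- 608 / S
    sig <- 1 / (1 + exp(-0.4055))
    expect_equal((d2$xMin[k] + d2$xMax[k]) / 2, (5 - 1 + sig) * stride,
                 tolerance = 1e-12)
    expect_equal((d2$yMin[k] + d2$yMax[k]) / 2, (3 - 1 + sig) * stride,
                 tolerance = 1e-12)
    expect_equal(d2$xMax[k] - d2$xMin[k], 20)  # anchor w 10 * exp(ln 2)
    expect_equal(d2$yMax[k] - d2$yMin[k], 14)

    raw3 <- array(0, dim = c(S, S, A, 7)); raw3[, , , 5] <- -10
    expect_true(all(decodeRaw(raw3, aset)$objectness < 1e-4))
    expect_error(decodeRaw(array(0, dim = c(4, 5, 3, 7)), aset), "S x S")
})

test_that("objectness filtering keeps scores at or above P and is monotone", {
    d <- spreadDetections(rep("seed", 3), c(0.05, 0.06, 0.9))
    expect_equal(objectnessFilter(d, 0.06)$objectness, c(0.06, 0.9))
    expect_equal(nrow(objectnessFilter(d, 0)), 3)
    expect_equal(nrow(objectnessFilter(d, 1)), 0)
    d1 <- spreadDetections("seed", 1)
    expect_equal(nrow(objectnessFilter(d1, 1)), 1)
    expect_error(objectnessFilter(d, 1.2), "\\[0, 1\\]")

    withr::with_seed(8, dd <- randomDetections(30))
    counts <- vapply(seq(0, 1, by = 0.05),
                     function(P) nrow(objectnessFilter(dd, P)), numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("nms suppresses class-wise and matches exhaustive search", {
    one <- spreadDetections("seed", 0.5)
    expect_equal(nms(one, 0.45), one)

    two <- detectionTable(data.frame(
        xMin = c(0, 1), yMin = c(0, 1), xMax = c(10, 11), yMax = c(10, 11),
        label = c("seed", "seed")), c(0.9, 0.8))
    kept <- nms(two, 0.45)
    expect_equal(nrow(kept), 1)
    expect_equal(kept$objectness, 0.9)

    cross <- detectionTable(data.frame(
        xMin = c(0, 0), yMin = c(0, 0), xMax = c(10, 10), yMax = c(10, 10),
        label = c("seed", "radicle")), c(0.9, 0.8))
    expect_equal(nrow(nms(cross, 0.45)), 2)

    withr::with_seed(21, {
        for (k in 1:200) {
            d <- randomDetections(sample(1:10, 1))
            got <- nms(d, 0.45)
            want <- d[oracleSuppress(d, 0.45), , drop = FALSE]
            expect_equal(got, want)
            # suppression-free: no retained same-class pair above threshold
            if (nrow(got) > 1) {
                M <- iouMatrix(got, got)
                sameClass <- outer(got$class, got$class, "==")
                diag(M) <- 0
                expect_true(all(M[sameClass] <= 0.45))
            }
        }
    })
})

test_that("letterboxing is aspect-preserving, padded, and invertible", {
    sq <- matrix(runif(100 * 100), 100, 100)
    lb <- letterbox(sq, 608)
    expect_equal(dim(lb$image), c(608, 608))
    expect_equal(lb$transform$padX, 0)
    expect_equal(lb$transform$padY, 0)

    # raw half-filter capture geometry: 2560 x 1920 -> 608 x 456 + 76 pad
    wide <- matrix(0.3, 1920, 2560)
    lw <- letterbox(wide, 608)
    expect_equal(lw$transform$scale, 608 / 2560)
    expect_equal(lw$transform$padY, 76)
    expect_equal(lw$transform$padX, 0)
    expect_equal(lw$image[1, 1], 0.5)    # padding is neutral gray
    expect_equal(lw$image[77, 1], 0.3)

    withr::with_seed(5, {
        b <- data.frame(xMin = runif(100, 0, 2000), yMin = runif(100, 0, 1500))
        b$xMax <- b$xMin + runif(100, 5, 300)
        b$yMax <- b$yMin + runif(100, 5, 300)
    })
    back <- unmapBoxes(mapBoxes(b, lw$transform), lw$transform)
    expect_lt(max(abs(as.matrix(back) - as.matrix(b))), 1)
})

test_that("the training recipe serializes with its exact defaults", {
    r <- trainingRecipe()
    txt <- writeTrainingRecipe(r)
    expect_match(txt, "momentum: 0.9")
    expect_match(txt, "learning_rate: 0.001")
    expect_match(txt, "weight_decay: (0.0005|5e-04)")
    expect_match(txt, "max_epochs: 20000")
    expect_match(txt, "- 16000")
    expect_match(txt, "- 18000")
    expect_match(txt, "input_resolution: 608")

    back <- readTrainingRecipe(txt)
    expect_equal(back@momentum, 0.9)
    expect_equal(back@learningRate, 1e-3)
    expect_equal(back@weightDecay, 5e-4)
    expect_equal(back@maxEpochs, 20000L)
    expect_equal(back@lrDropEpochs, c(16000L, 18000L))
    expect_equal(anchors(back), anchors(r))
    expect_equal(back@augmentation, r@augmentation)

    expect_error(new("TrainingRecipe", optimizer = "sgd", momentum = 0.9,
                     learningRate = 1e-3, weightDecay = 5e-4,
                     maxEpochs = 20000L, lrDropEpochs = 21000L,
                     lrDropFactor = 10, inputResolution = 608L,
                     augmentation = character(0),
                     anchors = trainingRecipe()@anchors),
                 "lrDropEpochs")
})

test_that("raw grids round-trip through the sidecar file format", {
    withr::with_seed(14, raw <- array(rnorm(5 * 5 * 3 * 7),
                                      dim = c(5, 5, 3, 7)))
    dir <- withr::local_tempdir()
    sc <- file.path(dir, "grid.yaml")
    writeRawGrid(raw, sc, resolution = 320)
    got <- readRawGrid(sc)
    expect_equal(got$raw, raw, tolerance = 1e-6)
    expect_equal(got$resolution, 320)
    aset <- anchorSet(cbind(w = c(10, 30, 60), h = c(14, 28, 55)))
    expect_equal(decodeRaw(got$raw, aset, 320),
                 decodeRaw(raw, aset, 320), tolerance = 1e-6)
})
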