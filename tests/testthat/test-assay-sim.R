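test_that("simulated scenes carry exactly the configured object counts", {
    sc <- simulateImage(testConfig(), rngSeed = 2)
    expect_equal(nBoxes(sc, "seed"), 10)
    expect_equal(nBoxes(sc, "radicle"), 5)  # fraction 0.5 of 10
    expect_equal(nBoxes(sc), 15)
    img <- sceneImage(sc)
    expect_equal(dim(img), c(600, 600))
    expect_true(all(img >= 0 & img <= 1))

    none <- simulateImage(testConfig(germinationFraction = 0), rngSeed = 3)
    expect_equal(nBoxes(none, "radicle"), 0)

    # every box lies inside the image and every radicle box overlaps
    # exactly one seed box (its own seed's pole)
    b <- boxes(sc)
    expect_true(all(b$xMin >= 0 & b$yMin >= 0 &
                    b$xMax <= 600 & b$yMax <= 600))
})

test_that("identical config and seed give bit-identical scenes", {
    a <- simulateImage(testConfig(), rngSeed = 77)
    b <- simulateImage(testConfig(), rngSeed = 77)
    expect_identical(sceneImage(a), sceneImage(b))
    expect_identical(boxes(a), boxes(b))

    c2 <- simulateImage(testConfig(), rngSeed = 78)
    expect_false(identical(sceneImage(a), sceneImage(c2)))
})

test_that("overcrowded configurations fail with a clear placement error", {
    expect_error(simulateImage(testConfig(nSeeds = 400,
                                          maxPlaceRetries = 20L)),
                 "lower nSeeds|non-overlapping")
})

test_that("dataset manifests match annotations and pool to the expected class ratio", {
    cfg <- simConfig(imageSize = 700L, filterDiameter = 650, nSeeds = 50,
                     germinationFraction = 0.4, debrisDensity = 0,
                     radicleLengthRange = c(20, 60))
    ds <- simulateDataset(cfg, 10, rngSeed = 41)
    expect_equal(nrow(ds$manifest), 10)
    for (i in c(1, 5, 10)) {
        expect_equal(ds$manifest$nSeeds[i],
                     nBoxes(ds$scenes[[i]], "seed"))
        expect_equal(ds$manifest$nRadicles[i],
                     nBoxes(ds$scenes[[i]], "radicle"))
    }
    ratio <- sum(ds$manifest$nSeeds) / sum(ds$manifest$nRadicles)
    expect_gte(ratio, 2.2)
    expect_lte(ratio, 2.8)

    one <- simulateDataset(cfg, 1, rngSeed = 41)
    expect_equal(one$manifest$nSeeds[1], nBoxes(one$scenes[[1]], "seed"))

    other <- simulateDataset(cfg, 1, rngSeed = 42)
    expect_false(identical(sceneImage(other$scenes[[1]]),
                           sceneImage(one$scenes[[1]])))
})

test_that("dataset statistics converge to the configured rates", {
    cfg <- simConfig(imageSize = 600L, filterDiameter = 560, nSeeds = 30,
                     germinationFraction = 0.4, debrisDensity = 0,
                     radicleLengthRange = c(20, 50))
    ds <- simulateDataset(cfg, 100, rngSeed = 314)
    meanSeeds <- mean(ds$manifest$nSeeds)
    fracGerm <- sum(ds$manifest$nRadicles) / sum(ds$manifest$nSeeds)
    expect_lt(abs(meanSeeds - 30) / 30, 0.10)
    expect_lt(abs(fracGerm - 0.4) / 0.4, 0.10)
})

test_that("image pairs split with the requested overlap and reconstruct", {
    sc <- simulateImage(testConfig(), rngSeed = 12)
    pr <- splitImagePair(sc, 200)
    expect_equal(nrow(pr$top), 400)      # floor((600 + 200)/2)
    expect_equal(nrow(pr$bottom), 400)
    expect_identical(pr$top[201:400, ], pr$bottom[1:200, ])

    ab <- splitImagePair(sc, 0)
    expect_equal(nrow(ab$top) + nrow(ab$bottom), 600)
    expect_error(splitImagePair(sc, 300), "height")
})

test_that("seed derivation mixes reproducibly and spreads", {
    s1 <- vapply(1:50, function(i) germVision:::deriveSeed(123, i),
                 integer(1))
    s2 <- vapply(1:50, function(i) germVision:::deriveSeed(123, i),
                 integer(1))
    expect_identical(s1, s2)
    expect_equal(anyDuplicated(s1), 0)
    expect_true(all(s1 > 0 & s1 < 2^31))
    expect_false(any(s1 == vapply(1:50, function(i)
        germVision:::deriveSeed(124, i), integer(1))))
})
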