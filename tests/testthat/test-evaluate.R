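predTable <- function(sample, pct) {
    data.frame(sample = sample, totalSeeds = 10, germinatedSeeds = 0,
               germinationPct = pct, stringsAsFactors = FALSE)
}
truthTable <- function(sample, pct) {
    data.frame(sample = sample, nSeeds = 10, nRadicles = 0,
               germinationPct = pct, stringsAsFactors = FALSE)
}

test_that("average germination difference is the mean absolute per-image gap", {
    p <- predTable(c("a", "b"), c(20, 10))
    t <- truthTable(c("a", "b"), c(25, 13))
    expect_equal(as.numeric(avgGermDiff(p, t)), 4)

    same <- truthTable(c("a", "b"), c(20, 10))
    expect_equal(as.numeric(avgGermDiff(p, same)), 0)

    expect_error(avgGermDiff(p, truthTable(c("x", "y"), c(1, 2))),
                 "no overlapping samples")

    # order invariance and NA exclusion with tally
    pNA <- predTable(c("a", "b", "c"), c(20, NA, 10))
    tNA <- truthTable(c("c", "a", "b"), c(13, 25, 40))
    v <- avgGermDiff(pNA, tNA)
    expect_equal(as.numeric(v), mean(c(5, 3)))
    expect_equal(attr(v, "nExcluded"), 1)
    expect_equal(attr(v, "nUsed"), 2)
})

test_that("average germination difference matches a brute-force oracle", {
    withr::with_seed(55, {
        for (rep in 1:5) {
            nm <- sprintf("img%02d", 1:50)
            p <- predTable(sample(nm), runif(50, 0, 100))
            t <- truthTable(sample(nm), runif(50, 0, 100))
            expect_equal(as.numeric(avgGermDiff(p, t)),
                         oracleMeanAbsDiff(p, t))
        }
    })
})

test_that("underestimation percentage reproduces the published pooled errors", {
    expect_equal(underestimationPct(4848, 4486), 7.467)
    expect_equal(underestimationPct(910, 851), 6.484)
    expect_equal(underestimationPct(100, 100), 0)
    expect_equal(underestimationPct(100, 120), -20)  # overestimation, signed
    expect_error(underestimationPct(0, 10), "> 0")
})

test_that("error histograms bin half-open with an overflow bin and sum to 100", {
    h <- errorHistogram(c(1, 2, 3))
    expect_equal(h$pct[1], 100)
    expect_equal(sum(h$pct), 100)

    h2 <- errorHistogram(c(1, 2, 6, 11))
    expect_equal(h2$pct[1:3], c(50, 25, 25))
    expect_equal(sum(h2$pct), 100)

    # boundary values go to the upper bin; >= maxEdge pools into overflow
    h3 <- errorHistogram(c(5, 10, 30, 45))
    expect_equal(h3$pct[2], 25)
    expect_equal(h3$pct[3], 25)
    expect_equal(h3$pct[nrow(h3)], 50)

    expect_error(errorHistogram(numeric(0)), "no per-image")
    expect_error(errorHistogram(c(-1, 2)), ">= 0")

    withr::with_seed(77, {
        for (rep in 1:5) {
            d <- runif(200, 0, 40)
            got <- errorHistogram(d)
            expect_equal(got$pct, oracleHistogram(d))
            expect_equal(sum(got$pct), 100, tolerance = 1e-10)
        }
    })
})

# detections for a two-image set where planted false positives carry
# graded sub-threshold objectness: P = 0.06 is the smallest grid point
# removing them all while keeping every true detection
plantedScoreSets <- function() {
    mk <- function(nSeed, nRad, fpObj) {
        true <- spreadDetections(c(rep("seed", nSeed), rep("radicle", nRad)),
                                 seq(0.2, 0.99, length.out = nSeed + nRad))
        fp <- spreadDetections(rep("radicle", length(fpObj)), fpObj,
                               gap = 60)
        fp[, c("yMin", "yMax")] <- fp[, c("yMin", "yMax")] + 500
        rbind(true, fp)
    }
    list(img1 = mk(20, 8, c(0.015, 0.025, 0.035, 0.045, 0.055)),
         img2 = mk(25, 10, c(0.012, 0.022, 0.032, 0.042, 0.052)))
}
plantedTruth <- function() groundTruthCounts(c("img1", "img2"),
                                             c(20, 25), c(8, 10))

test_that("threshold sweep selects the planted optimum, verified exhaustively", {
    sets <- plantedScoreSets()
    truth <- plantedTruth()
    sw <- sweepThreshold(sets, truth)
    expect_equal(selectedSetting(sw), 0.06)

    # exhaustive grid oracle: recount by direct filtering arithmetic
    for (P in seq(0.01, 0.10, by = 0.01)) {
        ds <- vapply(names(sets), function(nm) {
            d <- sets[[nm]][sets[[nm]]$objectness >= P, ]
            100 * sum(d$class == "radicle") / sum(d$class == "seed")
        }, numeric(1))
        want <- mean(abs(ds - truth$germinationPct))
        row <- sweepGrid(sw)[abs(sweepGrid(sw)$setting - P) < 1e-9, ]
        expect_equal(row$avgGermDiff, want, tolerance = 1e-9)
        expect_gte(row$avgGermDiff,
                   min(sweepGrid(sw)$avgGermDiff) - 1e-12)
    }

    # ties break toward the smallest P
    clean <- lapply(plantedScoreSets(), function(d)
        d[d$objectness >= 0.2, ])
    swTie <- sweepThreshold(clean, truth)
    expect_equal(selectedSetting(swTie), 0.01)

    one <- sweepThreshold(clean, truth, grid = 0.07)
    expect_equal(selectedSetting(one), 0.07)
    expect_error(sweepThreshold(clean, truth, grid = numeric(0)), "empty")
})

test_that("checkpoint sweep selects the lowest-error checkpoint at fixed P", {
    truth <- plantedTruth()
    base <- lapply(plantedScoreSets(), function(d) d[d$objectness >= 0.2, ])
    degrade <- function(sets, missRate, seed) {
        withr::with_seed(seed, lapply(sets, function(d) {
            drop <- runif(nrow(d)) < missRate & d$class == "radicle"
            d[!drop, ]
        }))
    }
    cks <- list(ep3000 = degrade(base, 0.5, 1),
                ep9000 = base,
                ep15000 = degrade(base, 0.3, 2))
    sw <- sweepCheckpoints(cks, truth, P = 0.05)
    expect_equal(selectedSetting(sw), "ep9000")
    expect_equal(sweepGrid(sw)$avgGermDiff[2], 0)

    single <- sweepCheckpoints(cks["ep3000"], truth)
    expect_equal(selectedSetting(single), "ep3000")

    same <- sweepCheckpoints(list(a = base, b = base, c = base), truth)
    expect_equal(selectedSetting(same), "a")  # earliest on ties
    expect_error(sweepCheckpoints(list(), truth), "no checkpoint")
})

test_that("the comparison table mirrors the published layout and signs", {
    tab <- comparisonTable(c(seed = 4848, radicle = 910),
                           c(seed = 4486, radicle = 851))
    expect_equal(tab$seeds, c(4848, 4486, 7.467))
    expect_equal(tab$radicles, c(910, 851, 6.484))

    eq <- comparisonTable(c(seed = 10, radicle = 5), c(seed = 10, radicle = 5))
    expect_equal(eq$seeds[3], 0)
    expect_equal(eq$radicles[3], 0)

    over <- comparisonTable(c(seed = 100, radicle = 10),
                            c(seed = 110, radicle = 12))
    expect_equal(over$seeds[3], -10)
    expect_equal(over$radicles[3], -20)
})

test_that("evaluation reports bundle metric, deviation, and histogram coherently", {
    p <- data.frame(sample = c("a", "b", "c"), totalSeeds = c(48, 50, 0),
                    germinatedSeeds = c(12, 20, 0),
                    germinationPct = c(25, 40, NA))
    t <- groundTruthCounts(c("a", "b", "c"), c(50, 50, 50), c(15, 20, 10))
    r <- evalReport(p, t, operatingPoint = list(model = "test", P = 0.06))
    expect_s4_class(r, "EvalReport")
    expect_equal(sum(r@histogram$pct), 100)
    expect_equal(r@nExcluded, 1)
    expect_equal(avgGermDiffValue(r), mean(c(5, 0)))
    # pooled underestimation over the matched images
    expect_equal(r@perClassDeviation[["seed"]],
                 as.numeric(underestimationPct(150, 98)))
    expect_error(evalReport(predTable("zz", 10), t), "missing samples")
})
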