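#' Construct a simulator configuration
#'
#' Defaults emulate the standard glass-fibre filter germination assay as
#' imaged through a dissecting microscope: a merged frame of about
#' 2500 x 2500 px containing a 13 mm filter disc (~2400 px at ~192 px/mm),
#' an average of 50 seeds per filter, seed bodies just under 200 um
#' (major axes 25-38 px), a 40 % germination fraction (which yields a
#' pooled seed:radicle annotation ratio of 2.5:1), thin curved radicles of
#' 20-120 px, and debris particles whose size and contrast overlap the
#' seeds.
#'
#' @param imageSize square image side in pixels.
#' @param filterDiameter filter-disc diameter in pixels.
#' @param nSeeds mean seeds per image.
#' @param germinationFraction fraction of seeds that germinate.
#' @param seedAxisRange range of seed major axes (px).
#' @param seedAspectRange range of minor/major axis ratios.
#' @param radicleLengthRange,radicleWidthRange radicle geometry (px).
#' @param debrisDensity expected debris particles per image.
#' @param backgroundLevel,discLevel,seedLevel grayscale levels in [0, 1].
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param maxPlaceRetries bounded retries for non-overlapping placement.
#' @return A \code{\link{SimConfig}}.
#' @examples
#' simConfig(imageSize = 600, filterDiameter = 560, nSeeds = 10)
#' @export
simConfig <- function(imageSize = 2500L, filterDiameter = 2400,
                      nSeeds = 50, germinationFraction = 0.40,
                      seedAxisRange = c(25, 38),
                      seedAspectRange = c(0.60, 0.85),
                      radicleLengthRange = c(20, 120),
                      radicleWidthRange = c(3, 6),
                      debrisDensity = 30,
                      backgroundLevel = 0.25, discLevel = 0.85,
                      seedLevel = 0.30, noiseSd = 0.02,
                      maxPlaceRetries = 100L) {
    new("SimConfig", imageSize = as.integer(imageSize),
        filterDiameter = as.numeric(filterDiameter),
        nSeeds = as.numeric(nSeeds),
        germinationFraction = as.numeric(germinationFraction),
        seedAxisRange = as.numeric(seedAxisRange),
        seedAspectRange = as.numeric(seedAspectRange),
        radicleLengthRange = as.numeric(radicleLengthRange),
        radicleWidthRange = as.numeric(radicleWidthRange),
        debrisDensity = as.numeric(debrisDensity),
        backgroundLevel = as.numeric(backgroundLevel),
        discLevel = as.numeric(discLevel),
        seedLevel = as.numeric(seedLevel),
        noiseSd = as.numeric(noiseSd),
        maxPlaceRetries = as.integer(maxPlaceRetries))
}

# Lehmer-style mixing of a master seed into per-image seeds; exact in
# doubles (48271 * 2147483646 < 2^53), hence reproducible across platforms.
deriveSeed <- function(master, i) {
    m <- 2147483647
    x <- ((as.numeric(master) %% (m - 1)) + i * 2654435) %% (m - 1) + 1
    as.integer((48271 * x) %% m)
}

# linear pixel indices of filled discs of radius r at each (y, x) path
# point; the caller assigns into the image in its own frame so the big
# matrix is modified in place
.pathIdx <- function(ys, xs, radii, h, w) {
    rmax <- ceiling(max(radii))
    off <- seq(-rmax, rmax)
    dy <- rep(off, times = length(off))
    dx <- rep(off, each = length(off))
    d2 <- dy^2 + dx^2
    idx <- vector("list", length(ys))
    for (k in seq_along(ys)) {
        sel <- d2 <= radii[k]^2
        yy <- round(ys[k]) + dy[sel]; xx <- round(xs[k]) + dx[sel]
        ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
        idx[[k]] <- (xx[ok] - 1) * h + yy[ok]
    }
    unique(unlist(idx))
}

# linear pixel indices of a filled rotated ellipse
.ellipseIdx <- function(cx, cy, a, b, theta, h, w) {
    ext <- ceiling(max(a, b)) + 1L
    rows <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
    cols <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
    X <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
    Y <- matrix(rows, length(rows), length(cols)) - cy
    u <- X * cos(theta) + Y * sin(theta)
    v <- -X * sin(theta) + Y * cos(theta)
    mask <- (u / a)^2 + (v / b)^2 <= 1
    R <- matrix(rows, length(rows), length(cols))
    C <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    (C[mask] - 1) * h + R[mask]
}

# axis-aligned bounding half-extents of a rotated ellipse
.ellipseExtents <- function(a, b, theta) {
    c(hw = sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
      hh = sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

#' Simulate one filter-assay scene with exact ground truth
#'
#' Renders a bright circular filter disc on a darker surround, places
#' exactly \code{round(nSeeds)} dark elliptical seeds with random
#' orientation and non-overlapping centers inside the disc, germinates
#' exactly \code{round(germinationFraction * n)} of them by attaching a
#' thin, tapering, curved radicle to one pole, scatters irregular debris
#' blobs, and adds Gaussian noise. The returned annotation is exact by
#' construction: one \code{seed} box per ellipse (its axis-aligned bounding
#' box) and one \code{radicle} box per germinated seed — a square of side
#' roughly the seed's minor axis centered on the seed-radicle junction,
#' which is how radicle onsets are annotated in the assay.
#'
#' Identical \code{(config, rngSeed)} pairs produce bit-identical scenes.
#'
#' @param config a \code{\link{SimConfig}}.
#' @param rngSeed integer seed.
#' @param imageId identifier for the annotation (default derived from the
#'   seed).
#' @param nSeedsOverride,nGermOverride exact counts overriding the config
#'   (used by \code{\link{simulateDataset}} to jitter per-image counts).
#' @return An \code{\link{AssayScene}}.
#' @examples
#' sc <- simulateImage(simConfig(imageSize = 400, filterDiameter = 380,
#'                               nSeeds = 5, debrisDensity = 0,
#'                               seedAxisRange = c(14, 20),
#'                               radicleLengthRange = c(12, 40)), rngSeed = 1)
#' nBoxes(sc, "seed")
#' @export
simulateImage <- function(config, rngSeed = 1L, imageId = NULL,
                          nSeedsOverride = NULL, nGermOverride = NULL) {
    stopifnot(is(config, "SimConfig"))
    if (is.null(imageId)) imageId <- sprintf("sim_%d", as.integer(rngSeed))
    n <- if (is.null(nSeedsOverride)) round(config@nSeeds) else
        as.integer(nSeedsOverride)
    nGerm <- if (is.null(nGermOverride))
        round(config@germinationFraction * n) else as.integer(nGermOverride)
    nGerm <- min(nGerm, n)
    sz <- config@imageSize
    R <- config@filterDiameter / 2
    ctr <- (sz + 1) / 2

    withr::with_seed(as.integer(rngSeed), {
        img <- matrix(config@backgroundLevel, sz, sz)
        d2 <- outer((seq_len(sz) - ctr)^2, (seq_len(sz) - ctr)^2, "+")
        img[d2 <= R^2] <- config@discLevel

        # --- seed placement: rejection sampling, non-overlapping ---
        major <- stats::runif(n, config@seedAxisRange[1],
                              config@seedAxisRange[2])
        aspect <- stats::runif(n, config@seedAspectRange[1],
                               config@seedAspectRange[2])
        theta <- stats::runif(n, 0, pi)
        a <- major / 2; b <- aspect * major / 2
        placeMargin <- 4
        cxs <- numeric(n); cys <- numeric(n)
        for (i in seq_len(n)) {
            placed <- FALSE
            for (try in seq_len(config@maxPlaceRetries)) {
                rr <- R - a[i] - 8
                if (rr <= 0) break
                ang <- stats::runif(1, 0, 2 * pi)
                rad <- sqrt(stats::runif(1)) * rr
                x <- ctr + rad * cos(ang); y <- ctr + rad * sin(ang)
                if (i == 1L || all(sqrt((cxs[seq_len(i - 1)] - x)^2 +
                                        (cys[seq_len(i - 1)] - y)^2) >
                                   a[seq_len(i - 1)] + a[i] + placeMargin)) {
                    cxs[i] <- x; cys[i] <- y; placed <- TRUE; break
                }
            }
            if (!placed)
                stop("could not place ", n, " non-overlapping seeds; ",
                     "lower nSeeds or enlarge the filter", call. = FALSE)
        }

        germIdx <- if (nGerm > 0) seq_len(nGerm) else integer(0)
        seedShade <- config@seedLevel + stats::runif(n, -0.03, 0.03)

        # --- radicle paths: curved polylines from one pole, kept clear of
        # other seeds and inside the disc ---
        radPaths <- vector("list", n)
        radWidth <- stats::runif(n, config@radicleWidthRange[1],
                                 config@radicleWidthRange[2])
        for (i in germIdx) {
            len <- stats::runif(1, config@radicleLengthRange[1],
                                config@radicleLengthRange[2])
            path <- NULL
            for (try in 1:40) {
                pole <- sample(c(-1, 1), 1)
                dir0 <- theta[i] + if (pole > 0) 0 else pi
                dir0 <- dir0 + stats::runif(1, -0.5, 0.5)
                curv <- stats::runif(1, -1.2, 1.2) / len
                tt <- seq(0, len, by = 0.75)
                angs <- dir0 + curv * tt
                px <- cxs[i] + pole * a[i] * cos(theta[i]) +
                    cumsum(c(0, diff(tt)) * cos(angs))
                py <- cys[i] + pole * a[i] * sin(theta[i]) +
                    cumsum(c(0, diff(tt)) * sin(angs))
                inside <- all((px - ctr)^2 + (py - ctr)^2 < (R - 4)^2)
                clear <- TRUE
                others <- setdiff(seq_len(n), i)
                if (length(others) && inside) {
                    dmin <- vapply(others, function(j)
                        min(sqrt((px - cxs[j])^2 + (py - cys[j])^2)),
                        numeric(1))
                    clear <- all(dmin > a[others] + radWidth[i] + 3)
                }
                if (inside && clear) {
                    path <- cbind(x = px, y = py)
                    break
                }
                if (try %% 10 == 0) len <- max(len / 2,
                                               config@radicleLengthRange[1])
            }
            if (is.null(path)) {
                # straight minimal stub toward the disc center as fallback
                dir0 <- atan2(ctr - cys[i], ctr - cxs[i])
                tt <- seq(0, config@radicleLengthRange[1], by = 0.75)
                path <- cbind(x = cxs[i] + a[i] * cos(dir0) + tt * cos(dir0),
                              y = cys[i] + a[i] * sin(dir0) + tt * sin(dir0))
            }
            radPaths[[i]] <- path
        }

        # --- render (index assignment keeps the big matrix in place) ---
        for (i in germIdx) {
            p <- radPaths[[i]]
            taper <- seq(1, 0.55, length.out = nrow(p))
            img[.pathIdx(p[, "y"], p[, "x"],
                         pmax(radWidth[i] / 2 * taper, 0.9),
                         sz, sz)] <- seedShade[i] + 0.07
        }
        for (i in seq_len(n))
            img[.ellipseIdx(cxs[i], cys[i], a[i], b[i], theta[i],
                            sz, sz)] <- seedShade[i]

        nDebris <- if (config@debrisDensity > 0)
            stats::rpois(1, config@debrisDensity) else 0L
        for (k in seq_len(nDebris)) {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- sqrt(stats::runif(1)) * (R - 20)
            dx <- ctr + rad * cos(ang); dy <- ctr + rad * sin(ang)
            shade <- stats::runif(1, config@seedLevel - 0.08,
                                  config@discLevel - 0.15)
            nl <- sample(2:4, 1)
            for (l in seq_len(nl)) {
                lr <- stats::runif(1, 2, 11)
                ox <- dx + stats::runif(1, -8, 8)
                oy <- dy + stats::runif(1, -8, 8)
                img[.ellipseIdx(ox, oy, lr, lr * stats::runif(1, 0.5, 1),
                                stats::runif(1, 0, pi), sz, sz)] <- shade
            }
        }

        if (config@noiseSd > 0)
            img <- img + matrix(stats::rnorm(sz * sz, 0, config@noiseSd),
                                sz, sz)
        img[img < 0] <- 0; img[img > 1] <- 1

        # --- exact annotation ---
        seedBoxes <- lapply(seq_len(n), function(i) {
            e <- .ellipseExtents(a[i], b[i], theta[i])
            data.frame(xMin = cxs[i] - e["hw"] - 0.5,
                       yMin = cys[i] - e["hh"] - 0.5,
                       xMax = cxs[i] + e["hw"] + 0.5,
                       yMax = cys[i] + e["hh"] + 0.5,
                       label = "seed", stringsAsFactors = FALSE)
        })
        radBoxes <- lapply(germIdx, function(i) {
            j <- radPaths[[i]][1, ] # seed-radicle junction
            side <- b[i] * 2
            data.frame(xMin = j["x"] - side / 2, yMin = j["y"] - side / 2,
                       xMax = j["x"] + side / 2, yMax = j["y"] + side / 2,
                       label = "radicle", stringsAsFactors = FALSE)
        })
        bx <- do.call(rbind, c(seedBoxes, radBoxes))
        if (is.null(bx)) bx <- emptyBoxes()
        bx$xMin <- pmax(bx$xMin, 0); bx$yMin <- pmax(bx$yMin, 0)
        bx$xMax <- pmin(bx$xMax, sz); bx$yMax <- pmin(bx$yMax, sz)
        new("AssayScene", image = img,
            annotation = imageAnnotation(imageId, sz, sz, bx),
            config = config, rngSeed = as.numeric(rngSeed))
    })
}

#' Simulate a dataset of assay scenes with a manifest
#'
#' Derives one reproducible seed per image from the master seed (a fixed
#' Lehmer-style mixing function, so datasets are identical across
#' platforms) and simulates \code{nImages} scenes. With
#' \code{jitterCounts = TRUE} (default) the per-image seed count is Poisson
#' around \code{nSeeds} and germination is binomial with the configured
#' fraction, emulating biological spread; with \code{FALSE} every image
#' carries the exact configured counts.
#'
#' @param config a \code{\link{SimConfig}}.
#' @param nImages number of scenes (>= 1).
#' @param rngSeed master integer seed.
#' @param jitterCounts logical, see above.
#' @return list with \code{scenes} (list of \code{\link{AssayScene}}) and
#'   \code{manifest} (per-image ground-truth counts: \code{sample},
#'   \code{nSeeds}, \code{nRadicles}, \code{germinationPct}).
#' @export
simulateDataset <- function(config, nImages, rngSeed = 1L,
                            jitterCounts = TRUE) {
    stopifnot(is(config, "SimConfig"), nImages >= 1)
    counts <- withr::with_seed(as.integer(rngSeed), {
        if (jitterCounts) {
            ns <- pmax(1L, stats::rpois(nImages, config@nSeeds))
            ng <- stats::rbinom(nImages, ns, config@germinationFraction)
        } else {
            ns <- rep(round(config@nSeeds), nImages)
            ng <- rep(round(config@germinationFraction * round(config@nSeeds)),
                      nImages)
        }
        list(ns = as.integer(ns), ng = as.integer(ng))
    })
    scenes <- lapply(seq_len(nImages), function(i)
        simulateImage(config, deriveSeed(rngSeed, i),
                      imageId = sprintf("sim_%04d", i),
                      nSeedsOverride = counts$ns[i],
                      nGermOverride = counts$ng[i]))
    manifest <- groundTruthCounts(
        vapply(scenes, imageId, character(1)),
        vapply(scenes, nBoxes, numeric(1), label = "seed"),
        vapply(scenes, nBoxes, numeric(1), label = "radicle"))
    list(scenes = scenes, manifest = manifest)
}

#' Split a scene into an overlapping top/bottom image pair
#'
#' Emulates the two-shot capture of a filter (top and bottom half imaged
#' separately) so the translation-only stitcher can be tested against a
#' known ground-truth overlap.
#'
#' @param scene an \code{\link{AssayScene}} or a numeric image matrix.
#' @param overlapPx number of shared rows; must be less than half the image
#'   height.
#' @return list with \code{top}, \code{bottom} (matrices) and
#'   \code{trueOverlap}.
#' @export
splitImagePair <- function(scene, overlapPx = 200L) {
    img <- if (is(scene, "AssayScene")) scene@image else scene
    h <- nrow(img)
    overlapPx <- as.integer(overlapPx)
    if (overlapPx < 0 || overlapPx >= h / 2)
        stop("overlapPx must be in [0, height/2)", call. = FALSE)
    hTop <- floor((h + overlapPx) / 2)
    list(top = img[seq_len(hTop), , drop = FALSE],
         bottom = img[(hTop - overlapPx + 1):h, , drop = FALSE],
         trueOverlap = overlapPx)
}
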