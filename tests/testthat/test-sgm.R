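test_that("census descriptors encode monotone-invariant local structure", {
  expect_true(all(censusTransform(matrix(2, 9, 9), 3) == FALSE))
  im <- smoothImage(12, 14, seed = 1)
  b1 <- censusTransform(im, 3)
  b2 <- censusTransform(1000 * im^3 + 5, 3)  # strictly monotone remap
  expect_identical(b1, b2)
  # a single bright pixel: its own descriptor flags every neighbour as
  # darker, while its neighbours (centered on 0) set no bits at all
  im2 <- matrix(0, 5, 5); im2[3, 3] <- 1
  b <- censusTransform(im2, 3)
  expect_equal(sum(b[3, 3, ]), 8)
  expect_equal(sum(b[2, 2, ]), 0)
  expect_equal(sum(b[3, 2, ]), 0)
  expect_error(censusTransform(matrix(0, 3, 3), 5), "window")
  expect_error(censusTransform(im, 4), "odd")
})

test_that("cost volume matches the R census/Hamming oracle and shift planes", {
  left <- smoothImage(10, 16, seed = 2)
  p <- sgmParams(dMin = 0, dMax = 3, censusWindow = 3)
  # identical views: zero cost on the d = 0 plane
  vol0 <- matchingCostVolume(left, left, p)
  expect_equal(max(vol0@costs[, , 1]), 0)
  # pure +2 px shift: zero cost on the d = 2 plane in the interior
  right <- cbind(left[, 3:16], left[, 1:2])  # content moved left by 2
  vol <- matchingCostVolume(left, right, p)
  expect_equal(max(vol@costs[3:8, 4:14, 3]), 0)
  # exact agreement with the R-level descriptors for every plane
  for (d in 0:3) {
    oracle <- censusCostOracle(left, right, 3, d)
    plane <- vol@costs[, , d + 1]
    expect_equal(plane[!is.na(oracle)], oracle[!is.na(oracle)])
    expect_true(all(plane[is.na(oracle)] == vol@sentinel))
  }
})

test_that("raw winner-take-all equals brute-force per-pixel search", {
  left <- smoothImage(16, 16, seed = 3, blurSigma = 1)
  right <- smoothImage(16, 16, seed = 4, blurSigma = 1)
  p <- sgmParams(dMin = 0, dMax = 7, censusWindow = 3)
  vol <- matchingCostVolume(left, right, p)
  wta <- winnerTakeAll(vol)
  for (r in c(1, 8, 16)) for (cc in c(9, 12, 16)) {
    costs <- vapply(0:7, function(d) {
      o <- censusCostOracle(left, right, 3, d)[r, cc]
      if (is.na(o)) vol@sentinel else o
    }, numeric(1))
    expect_equal(mapValues(wta)[r, cc], (0:7)[which.min(costs)])
  }
  # all-equal costs break ties toward dMin
  flat <- vol
  flat@costs[] <- 1
  expect_true(all(mapValues(winnerTakeAll(flat)) == 0))
})

test_that("WTA equals exhaustive argmin on random volumes", {
  withr::with_seed(11, {
    for (i in 1:5) {
      costs <- array(stats::runif(8 * 8 * 8), c(8, 8, 8))
      vol <- new("CostVolume", costs = costs, disparities = 2:9,
                 sentinel = 99, inBounds = matrix(TRUE, 8, 8))
      wta <- mapValues(winnerTakeAll(vol))
      oracle <- apply(costs, c(1, 2), which.min) + 1
      expect_equal(wta, oracle)
    }
  })
})

test_that("with zero penalties aggregation returns nPaths times the raw cost", {
  vol <- matchingCostVolume(smoothImage(8, 12, 5), smoothImage(8, 12, 6),
                            sgmParams(0, 3, censusWindow = 3))
  p0 <- sgmParams(0, 3, censusWindow = 3, P1 = 0, P2 = 1e-9)
  agg4 <- aggregateCostsSGM(vol, p0, paths = rbind(c(0, -1), c(0, 1),
                                                   c(-1, 0), c(1, 0)))
  expect_equal(agg4@costs, 4 * vol@costs, tolerance = 1e-6)
})

test_that("single-path aggregation matches the scanline DP oracle", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      N <- sample(4:10, 1); nd <- sample(2:5, 1)
      costs <- matrix(stats::runif(nd * N, 0, 10), nd, N)  # d x pixel
      P1 <- stats::runif(1, 0.1, 2); P2 <- P1 + stats::runif(1, 0.1, 5)
      vol <- new("CostVolume",
                 costs = array(t(costs), c(1, N, nd)),
                 disparities = seq_len(nd), sentinel = 1e6,
                 inBounds = matrix(TRUE, 1, N))
      p <- sgmParams(1, nd, P1 = P1, P2 = P2)
      agg <- aggregateCostsSGM(vol, p, paths = rbind(c(0, 1)))
      # the SGM normalization subtracts a d-independent constant per
      # pixel, so the per-pixel argmin must equal the forward DP's
      L <- dpForwardOracle(costs, P1, P2)
      expect_equal(c(mapValues(winnerTakeAll(agg))),
                   apply(L, 2, which.min))
      # and the optimal scanline energy is reproduced up to that constant
      offs <- agg@costs[1, , ] - t(L)
      expect_equal(apply(offs, 1, stats::var), rep(0, N), tolerance = 1e-18)
    }
  })
})

test_that("forward DP energy equals exhaustive enumeration on tiny instances", {
  withr::with_seed(31, {
    costs <- matrix(stats::runif(3 * 6, 0, 5), 3, 6)
    L <- dpForwardOracle(costs, 0.7, 2.3)
    expect_equal(min(L[, 6]), enumMinEnergy(costs, 0.7, 2.3))
  })
})

test_that("aggregation beats raw WTA on noisy piecewise-constant shifts", {
  base <- smoothImage(40, 80, seed = 7, blurSigma = 1)
  base <- base / max(base)
  # left half at disparity 2, right half at 4 (cols 43:44 are occluded by
  # the construction and excluded from scoring, as is the seam)
  right <- cbind(base[, 3:42], base[, 45:80], base[, 1:4])
  truth <- matrix(rep(c(2, 4), c(42, 38)), 40, 80, byrow = TRUE)
  withr::with_seed(8, {
    ln <- base + matrix(stats::rnorm(3200, 0, 0.02), 40)
    rn <- right + matrix(stats::rnorm(3200, 0, 0.02), 40)
  })
  p <- sgmParams(0, 6, censusWindow = 5, P1 = 2, P2 = 12,
                 subpixel = FALSE, lrTolerance = Inf)
  vol <- matchingCostVolume(ln, rn, p)
  raw <- mapValues(winnerTakeAll(vol))
  agg <- mapValues(winnerTakeAll(aggregateCostsSGM(vol, p)))
  interior <- cbind(rep(5:36, 56), rep(c(11:40, 47:72), each = 32))
  rawErr <- mean(raw[interior] != truth[interior])
  aggErr <- mean(agg[interior] != truth[interior])
  expect_lt(aggErr, rawErr)
  expect_lt(aggErr, 0.05)
})

test_that("sub-pixel refinement recovers parabolic and V-shaped minima", {
  mkvol <- function(cm, c0, cp) {
    costs <- array(10, c(1, 1, 5))
    costs[1, 1, 2:4] <- c(cm, c0, cp)
    new("CostVolume", costs = costs, disparities = 0:4, sentinel = 1e6,
        inBounds = matrix(TRUE, 1, 1))
  }
  int1 <- disparityMap(matrix(2, 1, 1), matrix(TRUE, 1, 1), c(-0.5, 4.5))
  # symmetric costs: zero offset either way
  expect_equal(mapValues(subpixelRefine(mkvol(5, 1, 5), int1))[1, 1], 2)
  # exact parabola with vertex at 2.3: C(d) = (d - 2.3)^2
  pv <- mkvol((1 - 2.3)^2, (2 - 2.3)^2, (3 - 2.3)^2)
  expect_equal(mapValues(subpixelRefine(pv, int1, "parabola"))[1, 1], 2.3)
  # exact V shape with vertex at 2.3: C(d) = |d - 2.3|
  vv <- mkvol(1.3, 0.3, 0.7)
  expect_equal(mapValues(subpixelRefine(vv, int1, "equiangular"))[1, 1],
               2.3)
  # degenerate (flat) triple keeps the integer
  expect_equal(mapValues(subpixelRefine(mkvol(1, 1, 1), int1))[1, 1], 2)
  # boundary winners are never refined
  int0 <- disparityMap(matrix(0, 1, 1), matrix(TRUE, 1, 1), c(-0.5, 4.5))
  expect_equal(mapValues(subpixelRefine(mkvol(5, 1, 4), int0))[1, 1], 0)
})

test_that("left-right consistency keeps matches and drops occlusions", {
  left <- smoothImage(24, 40, seed = 9)
  right <- cbind(left[, 4:40], left[, 1:3])  # +3 px disparity
  p <- sgmParams(0, 6, censusWindow = 5, lrTolerance = 1)
  d <- computeDisparity(left, right, p)
  interior <- mapValues(d)[5:20, 10:36]
  expect_true(all(abs(interior - 3) <= 0.5))
  expect_true(mean(validMask(d)[5:20, 10:36]) > 0.95)

  # true occlusion: a textured foreground patch at disparity 6 in front
  # of the d = 3 background hides the background strip just left of it
  # in the right view; those left-view pixels must be invalidated
  fg <- smoothImage(24, 40, seed = 19, blurSigma = 1)
  lOcc <- left; rOcc <- right
  lOcc[8:16, 21:28] <- 5 + fg[8:16, 21:28]
  rOcc[8:16, 15:22] <- 5 + fg[8:16, 21:28]       # same patch, d = 6
  pOcc <- sgmParams(0, 8, censusWindow = 5, P1 = 2, P2 = 12,
                    lrTolerance = 1)
  dOcc <- computeDisparity(lOcc, rOcc, pOcc)
  # occluded background zone: left cols just left of the patch
  expect_lt(mean(validMask(dOcc)[9:15, 18:20]), 0.5)
  # while the foreground patch itself matches at d = 6
  core <- mapValues(dOcc)[10:14, 23:26]
  expect_equal(stats::median(core), 6, tolerance = 0.2)

  # infinite tolerance keeps every in-bounds pixel
  dl <- disparityMap(matrix(2, 4, 8), matrix(TRUE, 4, 8), c(0, 4))
  dr <- disparityMap(matrix(4, 4, 8), matrix(TRUE, 4, 8), c(0, 6))
  expect_true(all(lrConsistency(dl, dr, Inf)[, 3:8]))
})

test_that("identical views yield zero disparity; integer shifts are exact", {
  im <- smoothImage(24, 32, seed = 10)
  p <- sgmParams(-2, 2, censusWindow = 5, subpixel = FALSE)
  d0 <- computeDisparity(im, im, p)
  expect_true(all(mapValues(d0)[validMask(d0)] == 0))

  p5 <- sgmParams(0, 8, censusWindow = 5, subpixel = FALSE)
  right <- cbind(im[, 6:32], im[, 1:5])
  d5 <- computeDisparity(im, right, p5)
  inner <- mapValues(d5)[4:21, 12:28]
  expect_true(all(inner == 5))  # WTA-stage error is exactly zero
})

test_that("fractional shifts are recovered within 0.25 px on average", {
  im <- smoothImage(32, 48, seed = 12, blurSigma = 2.5)
  p <- sgmParams(-3, 3, censusWindow = 7)
  errs <- vapply(seq(0.1, 0.9, by = 0.2), function(s) {
    right <- fftShiftRows(im, -s)  # content moves left: disparity +s
    d <- computeDisparity(im, right, p)
    sel <- validMask(d); sel[, c(1:8, 41:48)] <- FALSE
    mean(abs(mapValues(d)[sel] - s))
  }, numeric(1))
  expect_lt(mean(errs), 0.25)
  expect_true(all(errs < 0.35))
})

test_that("two-layer phantom disparity gap tracks b f dZ / Z^2", {
  rig <- stereoRig()
  pair <- renderStereoPair(makeTwoLayerPhantom(), rig,
                           mediumModel("LP1300"), noise = NULL)
  sr <- disparitySearchRange(rig)
  d <- computeDisparity(enhanceMultiscale(normalizeIntensity(pair$left)),
                        enhanceMultiscale(normalizeIntensity(pair$right)),
                        sgmParams(sr[1], sr[2]))
  lab <- pair$truth$labels
  layerMean <- function(ks)
    mean(mapValues(d)[lab %in% ks & validMask(d)])
  g <- layerMean(c(1, 3)) - layerMean(c(2, 4))   # upper minus lower
  Z <- rig@referenceDistance
  pred <- rig@baseline * rig@camera@focalLength * 1 / Z^2 /
    (rig@camera@pixelPitch * 1e-3)
  expect_equal(g, pred, tolerance = 0.3)
})
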