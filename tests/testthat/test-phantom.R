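rig <- stereoRig()

test_that("the canonical two-layer phantom matches its published design", {
  scn <- makeTwoLayerPhantom()
  expect_length(scn@tubes, 4)
  expect_equal(vapply(scn@tubes, function(t) 2 * t@radius, numeric(1)),
               rep(1.0, 4))                       # 1 mm diameter vessels
  z <- sort(vapply(scn@tubes, function(t) unique(t@centerline[, 3]),
                   numeric(1)))
  expect_equal(z, c(7.5, 7.5, 8.5, 8.5))          # two layers
  expect_equal(z[3] - z[2], 1.0)                  # 1 mm layer gap
  expect_equal(scn@extent, c(40, 30))
})

test_that("rendered tube disparity equals the b f / Z prediction (< 0.05 px)", {
  # sub-pixel intensity centroids of a noise-free, unblurred vertical tube
  scn <- vesselScene(list(tube(cbind(0.3, c(-5, 5)), radius = 0.5,
                               z = 7.5)),
                     extent = c(20, 16), surfaceOffset = -1.5)
  centroidCol <- function(im, row) {
    w <- im[row, ]
    sum(w * seq_along(w)) / sum(w)
  }
  l <- projectScene(scn, rig, "left")
  r <- projectScene(scn, rig, "right")
  row <- as.integer(rig@camera@principalPoint[2])
  dPx <- centroidCol(l, row) - centroidCol(r, row)
  Z <- 450 - 1.5 + 7.5
  dPred <- metricToPixelDisparity(distanceToDisparity(Z, rig), rig@camera)
  expect_lt(abs(dPx - dPred), 0.05)

  # a 1 mm depth step moves disparity by ~ b f dZ / Z^2 ~ 0.35 px
  scn2 <- vesselScene(list(tube(cbind(0.3, c(-5, 5)), radius = 0.5,
                                z = 8.5)),
                      extent = c(20, 16), surfaceOffset = -1.5)
  l2 <- projectScene(scn2, rig, "left")
  r2 <- projectScene(scn2, rig, "right")
  gap <- dPx - (centroidCol(l2, row) - centroidCol(r2, row))
  expect_equal(gap * rig@camera@pixelPitch * 1e-3,
               40 * 35 * 1 / Z^2, tolerance = 0.05)
})

test_that("the transverse chord profile has FWHM = r sqrt(3)", {
  r <- 0.55
  x <- seq(-1, 1, by = 1e-4)
  chord <- ifelse(abs(x) < r, 2 * sqrt(pmax(r^2 - x^2, 0)), 0)
  half <- range(x[chord >= max(chord) / 2])
  expect_equal(diff(half), r * sqrt(3), tolerance = 1e-3)
  # and the renderer reproduces it on a fine grid
  im <- nirstereo:::.renderTubeCpp(5, 2001, -1, 1e-3, 0, 1e-3,
                                   rbind(c(0, -1), c(0, 1)), r, 2L)
  prof <- im[3, ]
  halfR <- range(which(prof >= max(prof) / 2)) * 1e-3
  expect_equal(diff(halfR), r * sqrt(3), tolerance = 5e-3)
})

test_that("the medium model attenuates and blurs as calibrated", {
  im <- matrix(0, 201, 201); im[101, 101] <- 1
  # zero coefficients: identity
  med0 <- mediumModel("LP1400", muEff = 0, psfFwhmAt1mm = 0,
                      psfFwhmSlope = 0)
  expect_equal(applyMedium(im, 5, med0, 0.25), im)
  # LP1100: halved total signal at 4 mm; LP1300 at 2 mm
  s1100 <- sum(applyMedium(im, 4, mediumModel("LP1100"), 0.25))
  expect_equal(s1100, 0.5, tolerance = 1e-3)
  s1300 <- sum(applyMedium(im, 2, mediumModel("LP1300"), 0.25))
  expect_equal(s1300, 0.5, tolerance = 1e-3)
  # log attenuation is linear in depth with slope -muEff
  z <- 1:6
  s <- vapply(z, function(zz)
    sum(applyMedium(im, zz, mediumModel("LP1300"), 0.25)), numeric(1))
  fit <- stats::lm(log(s) ~ z)
  expect_equal(unname(stats::coef(fit)[2]), -log(2), tolerance = 1e-3)
  # noise-free attenuation fits exactly; silence the perfect-fit note
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)
})

test_that("detector noise is reproducible and has the declared variance", {
  im <- matrix(5000, 100, 100)
  nm <- noiseModel(photonScale = 0.5, readNoiseSd = 40, seed = 42)
  n1 <- addNoise(im, nm)
  n2 <- addNoise(im, nm)
  expect_identical(n1, n2)                       # fixed seed, same bits
  expect_false(identical(n1, addNoise(im, noiseModel(0.5, 40, seed = 43))))
  # flat-field variance ~ mean / photonScale + readNoiseSd^2
  v <- stats::var(c(n1))
  expect_equal(v, 5000 / 0.5 + 40^2, tolerance = 0.05)
  # noise-free limit returns the quantized input
  expect_equal(addNoise(im + 0.4, noiseModel(Inf, 0, seed = 1)), im)
})

test_that("stereo rendering produces consistent ground truth", {
  scn <- makeTwoLayerPhantom()
  pair <- renderStereoPair(scn, rig, medium = NULL, noise = NULL,
                           exposure = NULL)
  # truth mask equals the union of the projected footprints
  ideal <- projectScene(scn, rig, "left")
  expect_equal(pair$truth$mask, ideal > 0)
  expect_equal(sort(unique(c(pair$truth$labels))), 0:4)
  expect_equal(pair$truth$tubeDisplayDepths, c(-6, -7, -6, -7))
  # all four tubes visible in both views
  pairM <- renderStereoPair(scn, rig, mediumModel("LP1300"))
  for (k in 1:4) expect_gt(sum(pair$truth$labels == k), 100)
  expect_gt(min(pairM$left), -1e-9)
})

test_that("a noise-free phantom pair reconstructs depths within 0.3 mm", {
  pair <- renderStereoPair(makeTwoLayerPhantom(), rig,
                           mediumModel("LP1300"), noise = NULL)
  res <- suppressMessages(runPipeline(pair$left, pair$right))
  m <- depthRecoveryMetrics(res$depth, pair$truth)
  expect_true(all(abs(m$perVessel$meanErrorMm) < 0.3))
  expect_equal(m$layerSeparationMm, 1, tolerance = 0.3)
  # per-vessel mean depths ordered as ground truth (upper shallower)
  up <- m$perVessel$truthDepthMm == -6
  depths <- m$perVessel$truthDepthMm + m$perVessel$meanErrorMm
  expect_true(max(depths[!up]) < min(depths[up]))
})

test_that("the capillary depth series dims and broadens with depth", {
  ser <- makeCapillaryDepthSeries(1:6, mediumModel("LP1100"))
  peaks <- vapply(ser, function(s) max(s$image), numeric(1))
  expect_true(all(diff(peaks) < 0))
  fw <- vapply(ser, function(s) {
    ctr <- which(s$image == max(s$image), arr.ind = TRUE)[1, ]
    prof <- lineProfile(s$image, c(ctr[2] - 150, ctr[1]),
                        c(ctr[2] + 150, ctr[1]),
                        pixelSizeMm = s$pixelSizeMm)
    fitGaussianFwhm(prof, units = "mm")@fwhm
  }, numeric(1))
  expect_true(all(diff(fw) > 0))                  # strong LP1100 growth
  ser13 <- makeCapillaryDepthSeries(c(1, 6), mediumModel("LP1300"))
  fw13 <- vapply(ser13, function(s) {
    ctr <- which(s$image == max(s$image), arr.ind = TRUE)[1, ]
    prof <- lineProfile(s$image, c(ctr[2] - 150, ctr[1]),
                        c(ctr[2] + 150, ctr[1]),
                        pixelSizeMm = s$pixelSizeMm)
    fitGaussianFwhm(prof, units = "mm")@fwhm
  }, numeric(1))
  expect_lt(fw13[2] / fw13[1], 2)                 # LP1300 stays steady
})

test_that("out-of-field tubes are excluded with a warning", {
  scn <- vesselScene(list(tube(cbind(70, c(-5, 5)), radius = 0.5, z = 2)),
                     extent = c(160, 16), surfaceOffset = 0)
  expect_warning(im <- projectScene(scn, rig, "left"), "outside")
  expect_equal(max(im), 0)
})
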