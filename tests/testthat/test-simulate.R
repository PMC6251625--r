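test_that("camera calibration obeys its range, moments and determinism", {
  expect_error(makeCameraCalibration(c(16L, 16L), readnoiseVarRange = c(-1, 2)),
               "non-negative")
  # degenerate range: identically zero read noise
  cal0 <- makeCameraCalibration(c(32L, 32L), readnoiseVarRange = c(0, 0), seed = 1L)
  expect_true(all(readNoiseVarMap(cal0) == 0))
  # determinism under seed
  a <- makeCameraCalibration(c(24L, 24L), seed = 42L)
  b <- makeCameraCalibration(c(24L, 24L), seed = 42L)
  expect_identical(readNoiseVarMap(a), readNoiseVarMap(b))
  expect_false(identical(readNoiseVarMap(a),
                         readNoiseVarMap(makeCameraCalibration(c(24L, 24L), seed = 43L))))
  # uniform moments: mean of U(1,4) is 2.5, sd sqrt(9/12)
  v <- readNoiseVarMap(makeCameraCalibration(c(64L, 64L), readnoiseVarRange = c(1, 4),
                                             seed = 7L))
  se <- sqrt(9 / 12) / sqrt(length(v))
  expect_lt(abs(mean(v) - 2.5), 3 * se)
})

test_that("ground truth satisfies count, containment and radius invariants", {
  cfg <- simulationConfig(nClusters = 0L, backgroundDensity = 0, seed = 1L)
  expect_identical(nrow(emitters(simulateGroundTruth(cfg))), 0L)

  cfg <- simulationConfig(nClusters = 40L, moleculesPerCluster = 30L,
                          backgroundDensity = 0, seed = 2L)
  gt <- simulateGroundTruth(cfg)
  em <- emitters(gt)
  expect_identical(nrow(em), 1200L)
  expect_true(all(maskContains(nucleusMask(gt), em$x_nm, em$y_nm)))
  ctr <- clusterCenters(gt)
  d <- sqrt((em$x_nm - ctr$x_nm[em$cluster])^2 +
            (em$y_nm - ctr$y_nm[em$cluster])^2)
  expect_true(all(d <= 4 * cfg@clusterSigma + 1e-9))

  # background count is exact
  cfgB <- simulationConfig(nClusters = 2L, moleculesPerCluster = 3L,
                           backgroundDensity = 1.5, seed = 3L)
  gtB <- simulateGroundTruth(cfgB)
  nbg <- round(1.5 * maskArea(nucleusMask(gtB)))
  expect_identical(nrow(emitters(gtB)), as.integer(2 * 3 + nbg))

  # degenerate cluster width: members coincide with centres
  cfg0 <- simulationConfig(nClusters = 4L, moleculesPerCluster = 5L,
                           clusterSigma = 0, backgroundDensity = 0, seed = 4L)
  gt0 <- simulateGroundTruth(cfg0)
  em0 <- emitters(gt0); c0 <- clusterCenters(gt0)
  expect_equal(em0$x_nm, c0$x_nm[em0$cluster], tolerance = 1e-12)

  # oversized nucleus is rejected
  big <- ellipseMask(c(5000, 5000), c(1e5, 1e5))
  expect_error(simulateGroundTruth(cfg, mask = big), "fit")
})

test_that("blinking honours degenerate settings and determinism", {
  cfg <- simulationConfig(nClusters = 10L, moleculesPerCluster = 5L,
                          backgroundDensity = 0, nFrames = 50L, seed = 5L)
  gt <- simulateGroundTruth(cfg)
  cfgOff <- initialize(cfg, pOn = 0)
  expect_identical(nrow(simulateBlinking(gt, cfgOff)), 0L)

  cfgOn <- initialize(cfg, pOn = 1, meanOnFrames = 1, nFrames = 1L)
  act <- simulateBlinking(gt, cfgOn)
  expect_identical(sort(act$emitter), seq_len(nrow(emitters(gt))))
  expect_true(all(act$frame == 1L))

  expect_identical(simulateBlinking(gt, cfg), simulateBlinking(gt, cfg))
})

test_that("blinking activation counts match a brute-force two-state oracle", {
  nFrames <- 200L; pOn <- 0.01; meanOn <- 2
  cfg <- simulationConfig(nClusters = 100L, moleculesPerCluster = 10L,
                          backgroundDensity = 0, nFrames = nFrames,
                          pOn = pOn, meanOnFrames = meanOn, seed = 6L)
  gt <- simulateGroundTruth(cfg)
  act <- simulateBlinking(gt, cfg)
  # activation events = on-frames / mean run length; count starts directly
  starts <- sum(unlist(lapply(split(act$frame, act$emitter), function(f)
    1L + sum(diff(sort(f)) > 1L))))
  set.seed(10)
  oracle <- replicate(1000, bruteBlinkActivations(nFrames, pOn, meanOn))
  mu <- mean(oracle) * nrow(emitters(gt))
  sdTot <- sd(oracle) * sqrt(nrow(emitters(gt)))
  expect_lt(abs(starts - mu), 4 * sdTot)
})

test_that("rendering conserves photon flux and peaks at the emitter", {
  cfg <- simulationConfig(fieldSize = 32L, nClusters = 0L,
                          backgroundDensity = 0, nFrames = 1L,
                          bgPhotons = 0, seed = 7L)
  cal <- makeCameraCalibration(c(32L, 32L), gainMean = 2, offsetMean = 100,
                               readnoiseVarRange = c(0, 0), seed = 7L)
  gt <- simulateGroundTruth(cfg)
  # dark frame: every pixel equals the offset exactly
  dark <- renderStack(data.frame(emitter = integer(0), frame = integer(0),
                                 photons = numeric(0)),
                      gt, cfg, cal, shotNoise = FALSE, readNoise = FALSE)
  expect_equal(as.numeric(stackData(dark)[1, , ]),
               rep(100, 32 * 32), tolerance = 0)

  # single interior emitter on a pixel centre: flux conservation and peak
  gt@emitters <- data.frame(x_nm = 15 * cfg@pixelSize,
                            y_nm = 16 * cfg@pixelSize, cluster = 1L)
  act <- data.frame(emitter = 1L, frame = 1L, photons = 1234)
  st <- renderStack(act, gt, cfg, cal, shotNoise = FALSE, readNoise = FALSE)
  img <- (st@data[1, , ] - 100) / 2
  expect_equal(sum(img), 1234, tolerance = 1e-6)
  pk <- which(img == max(img), arr.ind = TRUE)
  expect_identical(as.integer(pk), c(17L, 16L))  # row = y + 1, col = x + 1
})

test_that("rendered pixel variance follows the shot + read noise decomposition", {
  n <- 32L; nRep <- 1500L
  cfg <- simulationConfig(fieldSize = n, nClusters = 0L, backgroundDensity = 0,
                          nFrames = nRep, bgPhotons = 0, pOn = 0, seed = 8L)
  cal <- makeCameraCalibration(c(n, n), gainMean = 2, offsetMean = 100,
                               readnoiseVarRange = c(2, 2), seed = 8L)
  gt <- simulateGroundTruth(cfg)
  gt@emitters <- data.frame(x_nm = 15 * cfg@pixelSize,
                            y_nm = 15 * cfg@pixelSize, cluster = 1L)
  act <- data.frame(emitter = rep(1L, nRep), frame = seq_len(nRep),
                    photons = rep(900, nRep))
  st <- renderStack(act, gt, cfg, cal, shotNoise = TRUE, readNoise = TRUE)
  mu <- expectedPsfImage(n, 15, 15, 900, 0, cfg@psfSigma / cfg@pixelSize)
  for (px in list(c(16L, 16L), c(16L, 15L), c(14L, 16L))) {
    vObs <- var(st@data[, px[1L], px[2L]])
    vExp <- 4 * (mu[px[1L], px[2L]] + 2)   # gain^2 (mu + v)
    expect_lt(abs(vObs / vExp - 1), 0.2)
  }
})

test_that("bead fields reproduce the warp and the Rayleigh noise law", {
  idm <- identityMapping()
  b0 <- simulateBeadField(50L, c(1e4, 1e4), idm, 0, seed = 1L)
  expect_equal(b0$mov_x_nm, b0$ref_x_nm, tolerance = 1e-12)
  expect_equal(b0$mov_y_nm, b0$ref_y_nm, tolerance = 1e-12)

  warp <- polynomialMapping(c(20, 1.001, 1e-4, 2e-9, -1e-9, 3e-9),
                            c(-10, 2e-4, 0.999, 1e-9, 2e-9, -2e-9))
  bw <- simulateBeadField(20L, c(1e4, 1e4), warp, 0, seed = 2L)
  direct <- applyMapping(warp, data.frame(x = bw$ref_x_nm, y = bw$ref_y_nm))
  expect_equal(bw$mov_x_nm, direct$x, tolerance = 1e-9)
  expect_equal(bw$mov_y_nm, direct$y, tolerance = 1e-9)

  bn <- simulateBeadField(10000L, c(1e4, 1e4), idm, 5, seed = 3L)
  d <- sqrt((bn$mov_x_nm - bn$ref_x_nm)^2 + (bn$mov_y_nm - bn$ref_y_nm)^2)
  rayleighMean <- 5 * sqrt(pi / 2)
  se <- 5 * sqrt((4 - pi) / 2) / sqrt(1e4)
  expect_lt(abs(mean(d) - rayleighMean), 4 * se)
})

test_that("fiber generator encodes the stall fraction it is given", {
  allStalled <- simulateFiberDataset(100L, 1, nReplicates = 1L, seed = 1L)
  expect_true(all(tracks(allStalled)$second_label_um == 0))

  none <- simulateFiberDataset(500L, 0, nReplicates = 1L, seed = 2L)
  expect_equal(percentStalled(none)$pooled$percent_stalled, 0)

  fd <- simulateFiberDataset(1000L, 0.2, nReplicates = 1L, seed = 3L)
  pct <- percentStalled(fd)$pooled$percent_stalled
  se <- 100 * sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(pct - 20), 3 * se)
  expect_error(simulateFiberDataset(10L, 1.5), "stallFraction")
})

test_that("identical config and seed give bit-identical simulations", {
  cfg <- simulationConfig(fieldSize = 32L, nClusters = 3L,
                          moleculesPerCluster = 4L, nFrames = 5L,
                          pOn = 0.2, seed = 99L)
  cal <- makeCameraCalibration(c(32L, 32L), seed = 99L)
  run <- function() {
    gt <- simulateGroundTruth(cfg)
    act <- simulateBlinking(gt, cfg)
    stackData(renderStack(act, gt, cfg, cal))
  }
  expect_identical(run(), run())
  cfg2 <- initialize(cfg, seed = 100L)
  gt2 <- simulateGroundTruth(cfg2)
  expect_false(identical(emitters(simulateGroundTruth(cfg)), emitters(gt2)))
})
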