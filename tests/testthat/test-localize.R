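test_that("box filter matches its definition and a brute-force convolution", {
  expect_error(boxFilter(matrix(0, 8, 8), 4), "odd")
  expect_equal(boxFilter(matrix(3.7, 10, 10), 3), matrix(3.7, 10, 10))

  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  f <- boxFilter(imp, 3)
  expect_equal(f[4:6, 4:6], matrix(1 / 9, 3, 3))
  expect_equal(sum(f), 1)

  set.seed(1)
  fr <- matrix(rnorm(64 * 64), 64, 64)
  for (w in c(3L, 5L))
    expect_equal(boxFilter(fr, w), bruteBoxFilter(fr, w), tolerance = 1e-10)
  # linearity
  fr2 <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(boxFilter(fr + 2 * fr2, 3),
               boxFilter(fr, 3) + 2 * boxFilter(fr2, 3), tolerance = 1e-12)
})

test_that("candidate detection finds isolated maxima and nothing on flats", {
  expect_error(detectCandidates(matrix(0, 5, 5), NA), "finite")
  expect_identical(nrow(detectCandidates(matrix(1, 20, 20), 0)), 0L)

  fr <- matrix(0, 40, 40); fr[10, 10] <- 5; fr[30, 30] <- 7
  cand <- detectCandidates(fr, 1, minSeparation = 5)
  expect_identical(cand$row, c(10L, 30L))
  expect_identical(cand$col, c(10L, 30L))

  # suppression keeps the stronger of two close peaks
  fr2 <- matrix(0, 20, 20); fr2[10, 10] <- 5; fr2[10, 12] <- 6
  c2 <- detectCandidates(fr2, 1, minSeparation = 5)
  expect_identical(nrow(c2), 1L)
  expect_identical(c2$col, 12L)
})

test_that("detection recalls simulated well-separated bright emitters", {
  n <- 96L
  cfg <- simulationConfig(fieldSize = n, nClusters = 0L, backgroundDensity = 0,
                          nFrames = 1L, bgPhotons = 10, seed = 21L)
  cal <- makeCameraCalibration(c(n, n), seed = 21L)
  gt <- simulateGroundTruth(cfg)
  set.seed(22)
  pos <- expand.grid(x = seq(8, 85, by = 11), y = seq(8, 85, by = 11))
  pos <- pos[sample(nrow(pos), 50), ]
  pos$x <- pos$x + runif(50, -1, 1); pos$y <- pos$y + runif(50, -1, 1)
  gt@emitters <- data.frame(x_nm = pos$x * cfg@pixelSize,
                            y_nm = pos$y * cfg@pixelSize,
                            cluster = seq_len(50))
  act <- data.frame(emitter = 1:50, frame = 1L, photons = 2000)
  st <- renderStack(act, gt, cfg, cal)
  photons <- (st@data[1, , ] - offsetMap(cal)) / gainMap(cal)
  filt <- boxFilter(photons, 3)
  cand <- detectCandidates(filt, detectionThreshold(filt), minSeparation = 5)
  hits <- sum(vapply(seq_len(50), function(i) {
    any(abs(cand$row - (pos$y[i] + 1)) <= 1 & abs(cand$col - (pos$x[i] + 1)) <= 1)
  }, logical(1L)))
  expect_gte(hits, 48L)
})

test_that("ROI segmentation converts to photons and enforces the border rule", {
  n <- 32L
  dat <- array(100, dim = c(1L, n, n))
  dat[1, 16, 16] <- 300
  stack <- new("FrameStack", data = dat, pixelSize = 110, channel = "A647",
               calibrationRef = "test")
  cal <- new("CameraCalibration", gain = matrix(2, n, n),
             offset = matrix(100, n, n), readnoiseVar = matrix(1.5, n, n))
  cand <- data.frame(frame = 1L, row = c(16L, 3L), col = c(16L, 16L))
  seg <- segmentRois(stack, cal, cand, roiSize = 11L)
  expect_identical(seg$log$kept, 1L)
  expect_identical(seg$log$border_dropped, 1L)
  patch <- matrix(seg$patches[1, ], 11, 11)
  expect_equal(patch[6, 6], 100)          # (300 - 100) / 2
  expect_equal(patch[1, 1], 0)
  expect_true(all(seg$varPatches == 1.5))
  expect_identical(c(seg$row0, seg$col0), c(10L, 10L))
})

test_that("MLE recovers noiseless parameters and respects mirror symmetry", {
  sg <- 1.3
  mu <- expectedPsfImage(11L, 5.3, 4.6, 1000, 5, sg)
  fit <- fitPsfMle(mu, matrix(0, 11, 11), sg)
  expect_true(fit$converged)
  expect_lt(abs(fit$x - 5.3), 0.01)
  expect_lt(abs(fit$y - 4.6), 0.01)
  expect_lt(abs(fit$N / 1000 - 1), 0.01)
  expect_lt(abs(fit$b / 5 - 1), 0.01)

  mirrored <- mu[, 11:1]
  fitM <- fitPsfMle(mirrored, matrix(0, 11, 11), sg)
  expect_equal(fitM$x, 10 - fit$x, tolerance = 1e-3)
  expect_equal(fitM$y, fit$y, tolerance = 1e-3)
})

test_that("estimator is unbiased with RMSE at the CRLB over noisy repeats", {
  sg <- 1.3; nRoi <- 1000L
  roi <- simulateRoiBatch(nRoi, N = 1000, b = 10, v = 2, sigmaPx = sg, seed = 31L)
  fit <- forkfocus:::fitPsfMleBatch(roi$patches, roi$varPatches, sg)
  expect_gt(mean(fit$converged), 0.99)
  bias <- mean(fit$x - roi$x)
  rmse <- sqrt(mean((fit$x - roi$x)^2))
  cr <- forkfocus:::crlbBatch(roi$x, roi$y, rep(1000, nRoi), rep(10, nRoi),
                              rep(sg, nRoi), roi$varPatches)
  expect_lt(abs(bias), 0.02)
  expect_lt(abs(rmse / mean(cr$x) - 1), 0.15)
})

test_that("CRLB obeys shot-noise scaling and noise monotonicity", {
  sg <- 1.3
  v0 <- matrix(0, 11, 11)
  c1 <- crlb(5, 5, 1000, 0, sg, v0)
  c4 <- crlb(5, 5, 4000, 0, sg, v0)
  expect_lt(abs(c1[["crlb_x"]] / c4[["crlb_x"]] - 2), 0.02 * 2)
  # shot-noise limit sigma / sqrt(N)
  expect_lt(abs(c1[["crlb_x"]] / (sg / sqrt(1000)) - 1), 0.05)
  # monotone in N, anti-monotone in v and b, on a grid
  grid <- expand.grid(N = c(200, 1000, 5000), v = c(0, 2, 5), b = c(0, 10))
  vals <- mapply(function(N, v, b)
    crlb(5, 5, N, b, sg, matrix(v, 11, 11))[["crlb_x"]],
    grid$N, grid$v, grid$b)
  for (vv in c(0, 2, 5)) for (bb in c(0, 10)) {
    sel <- grid$v == vv & grid$b == bb
    expect_true(all(diff(vals[sel][order(grid$N[sel])]) < 0))
  }
  for (NN in c(200, 1000, 5000)) {
    sel <- grid$N == NN & grid$b == 0
    expect_true(all(diff(vals[sel][order(grid$v[sel])]) > 0))
    selB <- grid$N == NN & grid$v == 0
    expect_true(all(diff(vals[selB][order(grid$b[selB])]) > 0))
  }
})

test_that("localization filtering is idempotent and fully logged", {
  rec <- data.frame(frame = 1:4, channel = "A647",
                    x_nm = c(100, 200, 300, 400), y_nm = c(100, 200, 300, 400),
                    photons = c(50, 500, 5000, 800),
                    background = 5, sigma_nm = 130,
                    crlb_x_nm = c(30, 20, 5, 80), crlb_y_nm = c(30, 20, 5, 80),
                    loglik = 0, converged = c(TRUE, TRUE, TRUE, FALSE))
  set <- new("LocalizationSet", records = rec, pixelSize = 110,
             source = "t", space = "camera:A647", filterLog = list())
  # disabled thresholds: identity
  all <- filterLocalizations(set, minPhotons = 0, maxCrlb = Inf,
                             requireConvergence = FALSE)
  expect_identical(locTable(all), rec)
  # everything rejected on photons
  none <- filterLocalizations(set, minPhotons = Inf)
  expect_identical(nrow(locTable(none)), 0L)
  expect_identical(filterLog(none)$rejected$photons, 4L)
  # defaults: photon, crlb and convergence rejections logged separately
  flt <- filterLocalizations(set)
  expect_identical(nrow(locTable(flt)), 2L)
  expect_identical(filterLog(flt)$rejected$photons, 1L)
  expect_identical(filterLog(flt)$rejected$crlb, 1L)
  expect_identical(filterLog(flt)$rejected$convergence, 0L)
  # idempotence
  again <- filterLocalizations(flt)
  expect_identical(locTable(again), locTable(flt))
})

test_that("localizeStack recalls bright, well-separated emitters precisely", {
  # bright (N >= 500) emitters separated by >= 4 PSF sigma, the regime the
  # single-emitter fitter is contracted for
  cfg <- simulationConfig(fieldSize = 96L, nClusters = 0L,
                          backgroundDensity = 0, nFrames = 5L, seed = 42L)
  cal <- makeCameraCalibration(c(96L, 96L), seed = 42L)
  gt <- simulateGroundTruth(cfg)
  set.seed(43)
  pos <- expand.grid(x = seq(8, 88, by = 8), y = seq(8, 88, by = 8))
  pos <- pos[sample(nrow(pos), 100), ]
  pos$x <- pos$x + runif(100, -1, 1); pos$y <- pos$y + runif(100, -1, 1)
  gt@emitters <- data.frame(x_nm = pos$x * cfg@pixelSize,
                            y_nm = pos$y * cfg@pixelSize, cluster = 0L)
  act <- data.frame(emitter = rep(1:100, 5), frame = rep(1:5, each = 100),
                    photons = round(runif(500, 500, 3000)))
  st <- renderStack(act, gt, cfg, cal)
  locs <- localizeStack(st, cal, psfSigma = cfg@psfSigma)
  rec <- locTable(locs)
  em <- emitters(gt)
  # precision: localizations match a truth emitter to within ~half a pixel
  good <- vapply(seq_len(nrow(rec)), function(i) {
    min(sqrt((em$x_nm - rec$x_nm[i])^2 + (em$y_nm - rec$y_nm[i])^2)) < 55
  }, logical(1L))
  expect_gte(mean(good), 0.95)
  # recall of the bright activations
  hit <- vapply(seq_len(nrow(act)), function(i) {
    r <- rec[rec$frame == act$frame[i], ]
    if (!nrow(r)) return(FALSE)
    min(sqrt((r$x_nm - em$x_nm[act$emitter[i]])^2 +
             (r$y_nm - em$y_nm[act$emitter[i]])^2)) < 55
  }, logical(1L))
  expect_gte(mean(hit), 0.90)
  # determinism of the full chain on a clustered blinking stack
  cfg2 <- simulationConfig(fieldSize = 64L, nClusters = 5L,
                           moleculesPerCluster = 20L, nFrames = 40L,
                           pOn = 0.004, seed = 41L)
  cal2 <- makeCameraCalibration(c(64L, 64L), seed = 41L)
  gt2 <- simulateGroundTruth(cfg2)
  st2 <- renderStack(simulateBlinking(gt2, cfg2), gt2, cfg2, cal2)
  l1 <- localizeStack(st2, cal2, psfSigma = cfg2@psfSigma)
  l2 <- localizeStack(st2, cal2, psfSigma = cfg2@psfSigma)
  expect_identical(locTable(l1), locTable(l2))
})

test_that("a stack without activations yields an empty localization set", {
  cfg <- simulationConfig(fieldSize = 48L, nClusters = 0L,
                          backgroundDensity = 0, nFrames = 5L, pOn = 0,
                          seed = 51L)
  cal <- makeCameraCalibration(c(48L, 48L), seed = 51L)
  gt <- simulateGroundTruth(cfg)
  st <- renderStack(simulateBlinking(gt, cfg), gt, cfg, cal)
  locs <- localizeStack(st, cal)
  expect_identical(nrow(locTable(locs)), 0L)
})
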