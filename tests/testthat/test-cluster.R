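test_that("binned pair counts match the all-pairs oracle exactly", {
  mk <- ellipseMask(c(2000, 2000), c(1800, 1500))
  set.seed(61)
  for (n in c(20L, 97L, 200L)) {
    pts <- forkfocus:::maskUniform(mk, n)
    breaks <- seq(0, 800, by = 25)
    fast <- forkfocus:::pairCounts(pts$x_nm, pts$y_nm, breaks, block = 33L)
    expect_identical(fast, brutePairHist(pts$x_nm, pts$y_nm, breaks))
  }
})

test_that("uniform points calibrate to g = 1 and clusters decay by 4 sigma", {
  mk <- ellipseMask(c(4000, 4000), c(3500, 2800))
  set.seed(62)
  pts <- forkfocus:::maskUniform(mk, 4000L)
  pr <- autoPairCorrelation(pts, mk, binWidth = 20, rMax = 600)
  expect_true(all(profileTable(pr)$g >= 0))
  expect_lt(mean(abs(pr@g - 1)), 0.08)
  expect_equal(pr@rho, 4000 / maskArea(mk))

  cfg <- clusterTestConfig(63L, background = 0, minSep = 200)
  gt <- simulateGroundTruth(cfg)
  prc <- autoPairCorrelation(emitters(gt), nucleusMask(gt),
                             binWidth = 10, rMax = 500)
  g <- prc@g; r <- prc@rCenters
  expect_gt(g[1L], 10)                       # strong short-range clustering
  expect_true(all(diff(g[r <= 3 * cfg@clusterSigma]) < 0))  # core decay
  beyond <- g[r > 4 * cfg@clusterSigma & r < 450]
  expect_lt(mean(abs(beyond - 1)), 0.5)      # near CSR past 4 sigma
})

test_that("pair-correlation preconditions are enforced", {
  mk <- ellipseMask(c(1000, 1000), c(900, 700))
  expect_error(autoPairCorrelation(data.frame(x = 1, y = 1), mk), "at least 2")
  pts <- data.frame(x = c(900, 1100), y = c(1000, 1000))
  expect_error(autoPairCorrelation(pts, mk, rMax = 1e5), "diameter")
})

test_that("cross-correlation is symmetric, flat for independence, high for identity", {
  mk <- ellipseMask(c(4000, 4000), c(3500, 2800))
  set.seed(64)
  a <- forkfocus:::maskUniform(mk, 1500L)
  b <- forkfocus:::maskUniform(mk, 1800L)
  w <- edgeWeights(mk, seq(0, 500, 25))
  cab <- crossPairCorrelation(a, b, mk, 25, 500, weights = w)
  cba <- crossPairCorrelation(b, a, mk, 25, 500, weights = w)
  expect_equal(cab@g, cba@g, tolerance = 1e-12)
  expect_lt(mean(abs(cab@g - 1)), 0.1)
  expect_identical(cab@kind, "cross")

  # identical sets: zero-distance pairs flood the smallest bin
  caa <- crossPairCorrelation(a, a, mk, 25, 500, weights = w)
  expect_gt(caa@g[1L], 10)

  # a pattern against itself displaced by d: flat below d / 2 (the
  # displaced copy of a CSR pattern has no short-range cross-correlation)
  set.seed(65)
  big <- forkfocus:::maskUniform(mk, 2500L)
  shifted <- data.frame(x = big$x_nm + 400, y = big$y_nm)
  wB <- edgeWeights(mk, seq(0, 180, 20))
  cd <- crossPairCorrelation(big, shifted, mk, 20, 180, weights = wB)
  expect_lt(mean(abs(cd@g - 1)), 0.2)

  # unregistered LocalizationSets are refused
  mkRec <- function(ch, sp) new("LocalizationSet",
    records = data.frame(frame = 1L, channel = ch, x_nm = c(1, 2),
                         y_nm = c(1, 2), photons = 500, background = 1,
                         sigma_nm = 130, crlb_x_nm = 9, crlb_y_nm = 9,
                         loglik = 0, converged = TRUE),
    pixelSize = 110, source = "s", space = sp, filterLog = list())
  expect_error(crossPairCorrelation(mkRec("A488", "camera:A488"),
                                    mkRec("A647", "camera:A647"), mk),
               "coordinate frames")
})

test_that("the cluster estimator is exact in the CSR limit and errors on cross profiles", {
  rc <- seq(5, 495, by = 10)
  csr <- new("PairCorrelationProfile", rCenters = rc, g = rep(1, length(rc)),
             binWidth = 10, rMax = 500, rho = 1000 / 50, nLocalizations = 1000L,
             maskArea = 50, kind = "auto")
  m <- fociPerNucleus(csr)
  expect_identical(moleculesPerClusterValue(m), 1)
  expect_identical(fociPerNucleusValue(m), 1000)

  cross <- initialize(csr, kind = "cross")
  expect_error(moleculesPerCluster(cross), "auto")
})

test_that("molecules per cluster and foci recover the generator truth", {
  w <- NULL
  for (seed in c(71L, 72L, 73L)) {
    cfg <- clusterTestConfig(seed, minSep = 200)
    gt <- simulateGroundTruth(cfg)
    if (is.null(w)) w <- edgeWeights(nucleusMask(gt), seq(0, 500, 10))
    pr <- autoPairCorrelation(emitters(gt), nucleusMask(gt), 10, 500, weights = w)
    m <- fociPerNucleus(pr)
    expect_lt(abs(moleculesPerClusterValue(m) / 30 - 1), 0.15)
    expect_lt(abs(fociPerNucleusValue(m) / 40 - 1), 0.15)
    # identity invariant
    expect_equal(fociPerNucleusValue(m) * moleculesPerClusterValue(m),
                 m@totalLocalizations, tolerance = 1e-9)
  }
})

test_that("recovery holds across a grid of cluster counts and sizes", {
  w <- edgeWeights(defaultNucleusMask(clusterTestConfig(1L)), seq(0, 500, 10))
  for (C in c(10L, 40L, 100L)) for (M in c(10L, 30L, 100L)) {
    cfg <- clusterTestConfig(7000L + C + M, nClusters = C, molecules = M,
                             background = 0)
    gt <- simulateGroundTruth(cfg)
    m <- fociPerNucleus(autoPairCorrelation(emitters(gt), nucleusMask(gt),
                                            10, 500, weights = w))
    expect_lt(abs(moleculesPerClusterValue(m) / M - 1), 0.15)
    expect_lt(abs(fociPerNucleusValue(m) / C - 1), 0.15)
  }
})

test_that("doubling molecules per cluster doubles the estimate", {
  cfgA <- clusterTestConfig(74L, molecules = 30L, background = 0, minSep = 200)
  cfgB <- clusterTestConfig(74L, molecules = 60L, background = 0, minSep = 200)
  gtA <- simulateGroundTruth(cfgA); gtB <- simulateGroundTruth(cfgB)
  w <- edgeWeights(nucleusMask(gtA), seq(0, 500, 10))
  nA <- moleculesPerCluster(autoPairCorrelation(emitters(gtA), nucleusMask(gtA),
                                                10, 500, weights = w))$value
  nB <- moleculesPerCluster(autoPairCorrelation(emitters(gtB), nucleusMask(gtB),
                                                10, 500, weights = w))$value
  expect_lt(abs(nB / nA - 2), 0.2 * 2)
})

test_that("condition comparison separates simulated knockdown from control", {
  mkMetrics <- function(cond, nClusters, molecules, seeds) {
    w <- NULL
    do.call(rbind, lapply(seeds, function(s) {
      cfg <- clusterTestConfig(s, nClusters = nClusters, molecules = molecules)
      gt <- simulateGroundTruth(cfg)
      if (is.null(w)) w <<- edgeWeights(nucleusMask(gt), seq(0, 500, 10))
      nucleusMetrics(emitters(gt), nucleusMask(gt), 10, 500, weights = w,
                     nucleusId = paste0(cond, s), condition = cond)
    }))
  }
  met <- rbind(mkMetrics("control", 40L, 30L, 101:110),
               mkMetrics("knockdown", 15L, 15L, 201:210))
  cmp <- conditionComparison(met, "control")
  foci <- cmp[cmp$metric == "foci_per_nucleus", ]
  expect_gt(foci$mean[foci$condition == "control"],
            foci$mean[foci$condition == "knockdown"])
  expect_lt(foci$welch_p_vs_control[foci$condition == "knockdown"], 0.01)
  mpc <- cmp[cmp$metric == "molecules_per_cluster", ]
  expect_gt(mpc$mean[mpc$condition == "control"],
            mpc$mean[mpc$condition == "knockdown"])

  # label symmetry: swapping labels swaps the group means
  met2 <- met
  met2$condition <- ifelse(met$condition == "control", "knockdown", "control")
  cmp2 <- conditionComparison(met2, "control")
  expect_equal(cmp2$mean[cmp2$metric == "foci_per_nucleus" &
                         cmp2$condition == "knockdown"],
               foci$mean[foci$condition == "control"])
  expect_error(conditionComparison(met, "absent"), "absent")
})
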