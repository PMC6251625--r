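# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by brute force rather than calling
# the code paths they check.

# Direct O(n^2 w^2) 2-D convolution with a normalized box kernel and
# mirror-reflected edges (edge row/col duplicated), the definition the fast
# separable implementation must reproduce.
bruteBoxFilter <- function(frame, width) {
  p <- (width - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  reflectIdx <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (dr in -p:p) for (dc in -p:p)
      acc <- acc + frame[reflectIdx(r + dr, nr), reflectIdx(cc + dc, nc)]
    out[r, cc] <- acc / width^2
  }
  out
}

# All-pairs distance histogram with the same binning convention as the
# chunked counter: unordered pairs, self-pairs excluded, bins (b_i, b_{i+1}]
# with distance 0 assigned to the first bin, distances >= max(breaks) dropped.
brutePairHist <- function(x, y, breaks) {
  n <- length(x)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  if (n < 2L) return(counts)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d >= breaks[nb + 1L]) next
    k <- findInterval(d, breaks, left.open = TRUE)
    if (d == 0) k <- 1L
    counts[k] <- counts[k] + 1
  }
  counts
}

# Expected pixel image of one integrated-Gaussian emitter (photon units),
# computed directly from normal CDFs. x, y in 0-based pixel coordinates.
expectedPsfImage <- function(nside, x, y, N, b, sigmaPx) {
  ex <- pnorm((0:(nside - 1L) + 0.5 - x) / sigmaPx) -
    pnorm((0:(nside - 1L) - 0.5 - x) / sigmaPx)
  ey <- pnorm((0:(nside - 1L) + 0.5 - y) / sigmaPx) -
    pnorm((0:(nside - 1L) - 0.5 - y) / sigmaPx)
  N * (ey %o% ex) + b
}

# Batch of noisy single-emitter ROIs (Poisson shot noise + Gaussian read
# noise of variance v), emitter jittered up to +/- 0.5 px about the centre.
simulateRoiBatch <- function(n, N, b, v, sigmaPx, nside = 11L, seed = 1L) {
  set.seed(seed)
  c0 <- (nside - 1) / 2
  x <- c0 + runif(n, -0.5, 0.5)
  y <- c0 + runif(n, -0.5, 0.5)
  P <- matrix(0, n, nside^2)
  for (i in seq_len(n)) {
    mu <- expectedPsfImage(nside, x[i], y[i], N, b, sigmaPx)
    obs <- matrix(rpois(nside^2, mu), nside, nside)
    if (v > 0) obs <- obs + matrix(rnorm(nside^2, 0, sqrt(v)), nside, nside)
    P[i, ] <- as.numeric(obs)
  }
  list(patches = P, varPatches = matrix(v, n, nside^2), x = x, y = y)
}

# Plain-loop two-state blinking simulation for one emitter; returns the
# number of activation events (off -> on transitions) in nFrames.
bruteBlinkActivations <- function(nFrames, pOn, meanOn) {
  pOff <- 1 / meanOn
  remaining <- 0L
  events <- 0L
  for (f in seq_len(nFrames)) {
    if (remaining == 0L) {
      if (runif(1) < pOn) {
        events <- events + 1L
        remaining <- rgeom(1, pOff) + 1L
      }
    }
    if (remaining > 0L) remaining <- remaining - 1L
  }
  events
}

# Shared Fig-5-like geometry for cluster tests. minSep > 0 gives the
# "well-separated foci" layout the recovery checks are premised on.
clusterTestConfig <- function(seed, nClusters = 40L, molecules = 30L,
                              background = 0.5, minSep = 0) {
  simulationConfig(nClusters = as.integer(nClusters),
                   moleculesPerCluster = as.integer(molecules),
                   backgroundDensity = background, minClusterSep = minSep,
                   seed = as.integer(seed))
}
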