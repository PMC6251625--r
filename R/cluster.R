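#' @include AllClasses.R utils.R
NULL

# Coordinates from a LocalizationSet or plain table.
coordsOf <- function(obj) {
  if (is(obj, "LocalizationSet")) {
    data.frame(x = obj@records$x_nm, y = obj@records$y_nm)
  } else asXY(obj)
}

# Exact binned pair-distance counts (unordered pairs, self-pairs excluded),
# chunked so n = 1e4 stays within memory. breaks are the bin edges;
# distances on an edge fall into the upper bin (left-open intervals),
# distances >= max(breaks) are ignored, distance exactly 0 goes to bin 1.
pairCounts <- function(x, y, breaks, block = 1024L) {
  n <- length(x)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  if (n < 2L) return(counts)
  rmax <- breaks[length(breaks)]
  starts <- seq(1L, n, by = block)
  for (bi in seq_along(starts)) {
    i0 <- starts[bi]; i1 <- min(i0 + block - 1L, n)
    xi <- x[i0:i1]; yi <- y[i0:i1]
    for (bj in bi:length(starts)) {
      j0 <- starts[bj]; j1 <- min(j0 + block - 1L, n)
      d2 <- outer(xi, x[j0:j1], `-`)^2 + outer(yi, y[j0:j1], `-`)^2
      if (bi == bj) d2[lower.tri(d2, diag = TRUE)] <- NA
      d <- sqrt(d2[!is.na(d2)])
      d <- d[d < rmax]
      if (length(d)) {
        idx <- findInterval(d, breaks, left.open = TRUE)
        idx[d == 0] <- 1L
        counts <- counts + tabulate(idx, nbins = nb)
      }
    }
  }
  counts
}

# Cross-pair counts between two point sets (all A-B pairs).
crossPairCounts <- function(xa, ya, xb, yb, breaks, block = 1024L) {
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  if (!length(xa) || !length(xb)) return(counts)
  rmax <- breaks[length(breaks)]
  for (i0 in seq(1L, length(xa), by = block)) {
    i1 <- min(i0 + block - 1L, length(xa))
    d2 <- outer(xa[i0:i1], xb, `-`)^2 + outer(ya[i0:i1], yb, `-`)^2
    d <- sqrt(as.numeric(d2))
    d <- d[d < rmax]
    if (length(d)) {
      idx <- findInterval(d, breaks, left.open = TRUE)
      idx[d == 0] <- 1L
      counts <- counts + tabulate(idx, nbins = nb)
    }
  }
  counts
}

#' Annulus-inside-mask edge-correction weights
#'
#' For each radial bin, the average (over a deterministic reference grid of
#' points inside the mask) fraction of the circle of the bin-centre radius
#' that lies inside the mask. This is the area-weighting that corrects
#' pair-correlation expectations for mask edges; it depends only on the
#' mask and binning, so it can be computed once and reused across nuclei
#' sharing a geometry.
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @param breaks radial bin edges (nm).
#' @param nRef target number of reference grid points.
#' @param nAngles circle sample count per reference point.
#' @return Numeric vector of per-bin weights in (0, 1].
#' @export
edgeWeights <- function(mask, breaks, nRef = 2048L, nAngles = 180L) {
  g <- maskRefGrid(mask, nRef)
  ang <- (seq_len(nAngles) - 0.5) * 2 * pi / nAngles
  ca <- cos(ang); sa <- sin(ang)
  rc <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  w <- numeric(length(rc))
  for (b in seq_along(rc)) {
    px <- outer(g$x, rc[b] * ca, `+`)
    py <- outer(g$y, rc[b] * sa, `+`)
    w[b] <- mean(maskContains(mask, as.numeric(px), as.numeric(py)))
  }
  pmax(w, 1e-6)
}

#' Auto-pair-correlation of localizations in a nucleus
#'
#' Estimates g(r) over radial annuli: observed pair counts divided by the
#' count expected under complete spatial randomness at the observed density,
#' with annulus-area-inside-mask edge correction. Self-pairs are excluded.
#' g = 1 at all r for a uniform (CSR) point pattern; short-range clustering
#' gives g >> 1 at small r.
#'
#' @param locs a \linkS4class{LocalizationSet} or a coordinate table with
#'   columns x/y or x_nm/y_nm (nm).
#' @param mask the \linkS4class{NucleusMask} the points live in.
#' @param binWidth radial bin width (nm, default 10).
#' @param rMax largest radius (nm, default 1000); must be below the mask
#'   diameter.
#' @param weights optional precomputed \code{\link{edgeWeights}} for this
#'   mask and binning.
#' @return A \linkS4class{PairCorrelationProfile} of kind "auto".
#' @export
#' @examples
#' mk <- ellipseMask(c(3000, 3000), c(2500, 2000))
#' set.seed(1); pts <- maskUniform(mk, 500)
#' pr <- autoPairCorrelation(pts, mk, binWidth = 50, rMax = 500)
#' mean(abs(profileTable(pr)$g - 1)) < 0.5
autoPairCorrelation <- function(locs, mask, binWidth = 10, rMax = 1000,
                                weights = NULL) {
  p <- coordsOf(locs)
  inside <- maskContains(mask, p$x, p$y)
  p <- p[inside, , drop = FALSE]
  n <- nrow(p)
  if (n < 2L) stop("need at least 2 localizations inside the mask")
  bb <- maskBBox(mask)
  if (rMax >= sqrt((bb[2L] - bb[1L])^2 + (bb[4L] - bb[3L])^2))
    stop("rMax must be below the mask diameter")
  breaks <- seq(0, rMax, by = binWidth)
  if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
  rc <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  if (is.null(weights)) weights <- edgeWeights(mask, breaks)
  counts <- pairCounts(p$x, p$y, breaks)
  areaNm2 <- maskArea(mask) * 1e6
  annArea <- pi * diff(breaks^2)
  expected <- (n * (n - 1) / 2) * annArea * weights / areaNm2
  new("PairCorrelationProfile", rCenters = rc, g = counts / expected,
      binWidth = binWidth, rMax = rMax, rho = n / maskArea(mask),
      nLocalizations = as.integer(n), maskArea = maskArea(mask),
      kind = "auto")
}

#' Cross-pair-correlation between two registered channels
#'
#' c(r): observed A-B pair counts divided by the expectation for
#' independent uniform A and B at their densities, with the same edge
#' correction as the auto profile. Symmetric in A and B. Both sets must be
#' in one coordinate frame (register the moving channel first); for
#' \linkS4class{LocalizationSet} inputs a differing \code{space} label is
#' an error.
#'
#' @param locsA,locsB localization sets or coordinate tables (nm).
#' @param mask the shared \linkS4class{NucleusMask}.
#' @param binWidth,rMax binning as in \code{\link{autoPairCorrelation}}.
#' @param weights optional precomputed \code{\link{edgeWeights}}.
#' @return A \linkS4class{PairCorrelationProfile} of kind "cross"; the
#'   density slot holds set A's density, \code{nLocalizations} set A's
#'   in-mask count.
#' @export
crossPairCorrelation <- function(locsA, locsB, mask, binWidth = 10,
                                 rMax = 1000, weights = NULL) {
  if (is(locsA, "LocalizationSet") && is(locsB, "LocalizationSet") &&
      !identical(locsA@space, locsB@space))
    stop(sprintf("channels are in different coordinate frames ('%s' vs '%s'); register them first",
                 locsA@space, locsB@space))
  a <- coordsOf(locsA); b <- coordsOf(locsB)
  a <- a[maskContains(mask, a$x, a$y), , drop = FALSE]
  b <- b[maskContains(mask, b$x, b$y), , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("both channels must be non-empty within the mask")
  breaks <- seq(0, rMax, by = binWidth)
  if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
  rc <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  if (is.null(weights)) weights <- edgeWeights(mask, breaks)
  counts <- crossPairCounts(a$x, a$y, b$x, b$y, breaks)
  areaNm2 <- maskArea(mask) * 1e6
  annArea <- pi * diff(breaks^2)
  expected <- nrow(a) * nrow(b) * annArea * weights / areaNm2
  new("PairCorrelationProfile", rCenters = rc, g = counts / expected,
      binWidth = binWidth, rMax = rMax, rho = nrow(a) / maskArea(mask),
      nLocalizations = as.integer(nrow(a)), maskArea = maskArea(mask),
      kind = "cross")
}

#' Average molecules per cluster from an auto profile
#'
#' The pair-correlation cluster estimator
#' \deqn{N_c = 1 + \rho \sum_b (g(r_b) - 1)\, 2 \pi r_b \, \Delta r,}
#' integrated from 0 to the first bin where g drops to 1 or below (capped
#' at rMax). The +1 makes the monomer (CSR) limit exact; the result is
#' floored at 1.
#'
#' @param profile an auto \linkS4class{PairCorrelationProfile} with
#'   positive density.
#' @param integrationRMax optional fixed upper limit (nm) overriding the
#'   first-crossing rule.
#' @return A list with \code{value} (N_c) and \code{integrationRMax} (nm).
#' @export
moleculesPerCluster <- function(profile, integrationRMax = NULL) {
  if (profile@kind != "auto")
    stop("cluster counting is defined for auto profiles only")
  if (profile@rho <= 0) stop("profile density must be positive")
  rc <- profile@rCenters
  g <- profile@g
  if (is.null(integrationRMax)) {
    cross <- which(g <= 1)
    lastBin <- if (length(cross)) cross[1L] - 1L else length(rc)
    integrationRMax <- if (lastBin >= 1L) rc[lastBin] + profile@binWidth / 2 else 0
  } else {
    lastBin <- sum(rc <= integrationRMax)
  }
  rhoNm2 <- profile@rho / 1e6
  nc <- 1
  if (lastBin >= 1L) {
    sel <- seq_len(lastBin)
    nc <- 1 + rhoNm2 * sum((g[sel] - 1) * 2 * pi * rc[sel] * profile@binWidth)
  }
  list(value = max(nc, 1), integrationRMax = integrationRMax)
}

#' Foci per nucleus from a profile and its localization count
#'
#' Divides the (relative) total number of localizations in the nucleus by
#' the average number of molecules per cluster. No blinking correction is
#' applied: counts are relative, and comparisons across conditions rely on
#' ratios.
#'
#' @param profile an auto \linkS4class{PairCorrelationProfile}.
#' @param integrationRMax optional override passed on to
#'   \code{\link{moleculesPerCluster}}.
#' @return A \linkS4class{ClusterMetrics}.
#' @export
fociPerNucleus <- function(profile, integrationRMax = NULL) {
  mc <- moleculesPerCluster(profile, integrationRMax)
  n <- profile@nLocalizations
  new("ClusterMetrics", moleculesPerCluster = mc$value,
      totalLocalizations = n, fociPerNucleus = n / mc$value,
      rho = profile@rho, integrationRMax = mc$integrationRMax)
}

#' Per-nucleus cluster metrics in one call
#'
#' Convenience wrapper: auto-pair-correlation then
#' \code{\link{fociPerNucleus}}, returned as a one-row data.frame ready to
#' stack across nuclei.
#'
#' @param locs localizations or coordinates (nm).
#' @param mask the nucleus \linkS4class{NucleusMask}.
#' @param binWidth,rMax,weights see \code{\link{autoPairCorrelation}}.
#' @param nucleusId,condition labels carried into the output row.
#' @return data.frame(nucleus_id, condition, n_locs, rho,
#'   molecules_per_cluster, foci_per_nucleus).
#' @export
nucleusMetrics <- function(locs, mask, binWidth = 10, rMax = 1000,
                           weights = NULL, nucleusId = "nucleus",
                           condition = "control") {
  pr <- autoPairCorrelation(locs, mask, binWidth, rMax, weights)
  m <- fociPerNucleus(pr)
  data.frame(nucleus_id = nucleusId, condition = condition,
             n_locs = m@totalLocalizations, rho = m@rho,
             molecules_per_cluster = m@moleculesPerCluster,
             foci_per_nucleus = m@fociPerNucleus)
}

#' Compare cluster metrics between conditions
#'
#' Per-condition mean, s.d. and n of foci-per-nucleus and
#' molecules-per-cluster across nuclei, with pairwise Welch t-tests of each
#' condition against a designated control.
#'
#' @param metrics data.frame as produced by stacking
#'   \code{\link{nucleusMetrics}} rows.
#' @param control the control condition label.
#' @return data.frame, one row per condition and metric, with mean, sd, n
#'   and the Welch p-value against the control (NA for the control itself;
#'   flagged NA with a warning when a condition has a single nucleus).
#' @export
conditionComparison <- function(metrics, control) {
  if (!control %in% metrics$condition)
    stop(sprintf("control condition '%s' absent from the metrics", control))
  conds <- unique(metrics$condition)
  out <- list()
  for (metric in c("foci_per_nucleus", "molecules_per_cluster")) {
    ctrlVals <- metrics[[metric]][metrics$condition == control]
    for (cond in conds) {
      v <- metrics[[metric]][metrics$condition == cond]
      if (length(v) < 2L)
        warning(sprintf("condition '%s' has a single nucleus: s.d. undefined", cond))
      p <- if (cond == control || length(v) < 2L || length(ctrlVals) < 2L)
        NA_real_
      else stats::t.test(v, ctrlVals, var.equal = FALSE)$p.value
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, condition = cond, mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        n = length(v), welch_p_vs_control = p)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
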