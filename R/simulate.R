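#' @include AllClasses.R utils.R
NULL

#' Create a simulation configuration
#'
#' Defaults encode the emulated study conditions: a 96 px field at 110 nm
#' pixels, 40 label clusters ("foci") of 30 fluorophores each (1:1 tagged
#' EdU), a sparse monomer background, two-state blinking imaged at 33 Hz for
#' 2000 frames, and a ~100 nm Gaussian PSF.
#'
#' @param fieldSize field side length in pixels.
#' @param pixelSize nm per pixel.
#' @param nClusters number of clusters per nucleus.
#' @param moleculesPerCluster fluorophores per cluster.
#' @param clusterSigma cluster Gaussian s.d. (nm).
#' @param minClusterSep minimum centre-to-centre cluster distance in nm
#'   (0 = uniform placement; a positive value gives a hard-core,
#'   well-separated focus layout).
#' @param backgroundDensity unclustered monomer density (per um^2).
#' @param nFrames frames per acquisition.
#' @param frameRateHz acquisition rate, metadata only.
#' @param pOn per-frame activation probability while off.
#' @param meanOnFrames mean consecutive on-frames per activation.
#' @param photonsMean expected photons per on-frame.
#' @param psfSigma PSF Gaussian s.d. (nm).
#' @param bgPhotons uniform background photons per pixel per frame.
#' @param seed master seed; identical config + seed gives bit-identical output.
#' @return A \linkS4class{SimulationConfig}.
#' @export
#' @examples
#' cfg <- simulationConfig(nClusters = 5L, nFrames = 10L)
simulationConfig <- function(fieldSize = 96L, pixelSize = 110,
                             nClusters = 40L, moleculesPerCluster = 30L,
                             clusterSigma = 25, minClusterSep = 0,
                             backgroundDensity = 0.5,
                             nFrames = 2000L, frameRateHz = 33,
                             pOn = 0.002, meanOnFrames = 2,
                             photonsMean = 2000, psfSigma = 100,
                             bgPhotons = 2, seed = 1L) {
  new("SimulationConfig", fieldSize = as.integer(fieldSize),
      pixelSize = as.numeric(pixelSize), nClusters = as.integer(nClusters),
      moleculesPerCluster = as.integer(moleculesPerCluster),
      clusterSigma = as.numeric(clusterSigma),
      minClusterSep = as.numeric(minClusterSep),
      backgroundDensity = as.numeric(backgroundDensity),
      nFrames = as.integer(nFrames), frameRateHz = as.numeric(frameRateHz),
      pOn = as.numeric(pOn), meanOnFrames = as.numeric(meanOnFrames),
      photonsMean = as.numeric(photonsMean), psfSigma = as.numeric(psfSigma),
      bgPhotons = as.numeric(bgPhotons), seed = as.integer(seed))
}

#' Simulate a per-pixel sCMOS calibration
#'
#' Read-noise variance is drawn independently and uniformly per pixel from
#' \code{readnoiseVarRange} (the "patterned" heterogeneity of an sCMOS
#' sensor); gain and offset are optionally jittered around their means.
#'
#' @param shape length-2 integer, (rows, cols).
#' @param gainMean mean gain (ADU per photon).
#' @param offsetMean mean offset (ADU).
#' @param readnoiseVarRange length-2 numeric, uniform variance range in
#'   photon-equivalent units; must be non-negative.
#' @param seed integer seed.
#' @param gainSd,offsetSd optional per-pixel Gaussian jitter (s.d.).
#' @return A \linkS4class{CameraCalibration}.
#' @export
#' @examples
#' cal <- makeCameraCalibration(c(32L, 32L), 2, 100, c(1, 4), seed = 1L)
makeCameraCalibration <- function(shape, gainMean = 2, offsetMean = 100,
                                  readnoiseVarRange = c(1, 4), seed = 1L,
                                  gainSd = 0, offsetSd = 0) {
  if (length(shape) != 2L || any(shape < 1))
    stop("shape must be two positive pixel dimensions")
  if (length(readnoiseVarRange) != 2L || any(readnoiseVarRange < 0) ||
      diff(readnoiseVarRange) < 0)
    stop("readnoiseVarRange must be a non-negative, non-decreasing interval")
  set.seed(substreamSeed(seed, "calibration"))
  np <- prod(shape)
  v <- matrix(stats::runif(np, readnoiseVarRange[1L], readnoiseVarRange[2L]),
              shape[1L], shape[2L])
  g <- matrix(gainMean + if (gainSd > 0) stats::rnorm(np, 0, gainSd) else 0,
              shape[1L], shape[2L])
  o <- matrix(offsetMean + if (offsetSd > 0) stats::rnorm(np, 0, offsetSd) else 0,
              shape[1L], shape[2L])
  if (any(g <= 0)) stop("gain jitter produced non-positive gains; reduce gainSd")
  new("CameraCalibration", gain = g, offset = o, readnoiseVar = v)
}

#' Default elliptical nucleus for a field
#'
#' An ellipse centred in the field with semi-axes 0.4 and 0.3 of the field
#' extent, leaving a margin so the whole nucleus is imaged.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{NucleusMask}.
#' @export
defaultNucleusMask <- function(config) {
  ext <- config@fieldSize * config@pixelSize
  ellipseMask(center = c(ext, ext) / 2, semiaxes = c(0.4, 0.3) * ext)
}

#' Simulate ground-truth emitter positions
#'
#' Cluster centres are uniform in the nucleus mask; members are isotropic
#' Gaussian (s.d. \code{clusterSigma}) around their centre, rejection-sampled
#' into the mask and truncated at 4 cluster radii; background monomers
#' (cluster id 0) are uniform in the mask. The emitter count is exactly
#' \code{nClusters * moleculesPerCluster + nBackground}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param mask optional \linkS4class{NucleusMask}; default
#'   \code{defaultNucleusMask(config)}.
#' @return A \linkS4class{GroundTruthField}.
#' @export
#' @examples
#' gt <- simulateGroundTruth(simulationConfig(nClusters = 3L,
#'   moleculesPerCluster = 5L, backgroundDensity = 0))
#' nrow(emitters(gt))  # 15
simulateGroundTruth <- function(config, mask = NULL) {
  if (is.null(mask)) mask <- defaultNucleusMask(config)
  ext <- config@fieldSize * config@pixelSize
  bb <- maskBBox(mask)
  if (bb[1L] < -config@pixelSize / 2 || bb[3L] < -config@pixelSize / 2 ||
      bb[2L] > ext || bb[4L] > ext)
    stop("nucleus mask does not fit inside the field")
  set.seed(substreamSeed(config@seed, "ground-truth"))
  centers <- if (config@minClusterSep > 0)
    maskHardcore(mask, config@nClusters, config@minClusterSep)
  else maskUniform(mask, config@nClusters)
  emit <- vector("list", config@nClusters + 1L)
  sc <- config@clusterSigma
  for (i in seq_len(config@nClusters)) {
    m <- config@moleculesPerCluster
    if (sc == 0) {
      pts <- data.frame(x_nm = rep(centers$x_nm[i], m),
                        y_nm = rep(centers$y_nm[i], m))
    } else {
      pts <- data.frame(x_nm = numeric(0), y_nm = numeric(0))
      while (nrow(pts) < m) {
        k <- max(2L * (m - nrow(pts)), 8L)
        x <- centers$x_nm[i] + stats::rnorm(k, 0, sc)
        y <- centers$y_nm[i] + stats::rnorm(k, 0, sc)
        keep <- maskContains(mask, x, y) &
          ((x - centers$x_nm[i])^2 + (y - centers$y_nm[i])^2 <= (4 * sc)^2)
        pts <- rbind(pts, data.frame(x_nm = x[keep], y_nm = y[keep]))
      }
      pts <- pts[seq_len(m), , drop = FALSE]
    }
    pts$cluster <- i
    emit[[i]] <- pts
  }
  nbg <- round(config@backgroundDensity * maskArea(mask))
  if (nbg > 0) {
    bg <- maskUniform(mask, nbg)
    bg$cluster <- 0L
    emit[[config@nClusters + 1L]] <- bg
  }
  em <- do.call(rbind, emit)
  if (is.null(em)) em <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                                    cluster = integer(0))
  rownames(em) <- NULL
  new("GroundTruthField", mask = mask, emitters = em,
      clusterCenters = centers, config = config)
}

#' Simulate two-state blinking
#'
#' Each emitter, while off, activates in a frame with probability \code{pOn};
#' once on it stays on for a geometric number of frames with mean
#' \code{meanOnFrames}; each on-frame emits Poisson(\code{photonsMean})
#' photons. Memoryless photophysics, no bleaching.
#'
#' @param field a \linkS4class{GroundTruthField}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame with columns emitter, frame, photons (one row per
#'   emitter on-frame), ordered by frame then emitter.
#' @export
simulateBlinking <- function(field, config) {
  if (config@nFrames < 1L) stop("nFrames must be >= 1")
  if (config@pOn < 0 || config@pOn > 1) stop("pOn must lie in [0, 1]")
  set.seed(substreamSeed(config@seed, "blinking"))
  nE <- nrow(field@emitters)
  if (nE == 0L || config@pOn == 0)
    return(data.frame(emitter = integer(0), frame = integer(0),
                      photons = numeric(0)))
  pOff <- 1 / config@meanOnFrames
  remaining <- integer(nE)           # on-frames left, 0 = off
  rows <- vector("list", config@nFrames)
  for (f in seq_len(config@nFrames)) {
    off <- remaining == 0L
    if (any(off)) {
      act <- off & (stats::runif(nE) < config@pOn)
      nAct <- sum(act)
      if (nAct)
        remaining[act] <- stats::rgeom(nAct, pOff) + 1L
    }
    on <- which(remaining > 0L)
    if (length(on)) {
      rows[[f]] <- data.frame(emitter = on, frame = f,
                              photons = stats::rpois(length(on), config@photonsMean))
      remaining[on] <- remaining[on] - 1L
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(emitter = integer(0), frame = integer(0),
                                      photons = numeric(0))
  rownames(out) <- NULL
  out
}

# Integrated symmetric 2-D Gaussian PSF over unit pixels.
# j, i are 0-based column/row indices; cx, cy the emitter position in the
# same continuous 0-based pixel coordinates (pixel j covers [j-0.5, j+0.5]).
intGaussPixels <- function(idx, c0, sigma) {
  stats::pnorm((idx + 0.5 - c0) / sigma) - stats::pnorm((idx - 0.5 - c0) / sigma)
}

#' Render a camera stack from an activation table
#'
#' Each active emitter contributes an integrated symmetric 2-D Gaussian PSF
#' of its photon count; pixel values follow the sCMOS model
#' \code{gain * Poisson(mu) + gain * Normal(0, sqrt(v)) + offset}, with
#' \code{mu} the expected photons (PSFs plus uniform background) and
#' \code{v} the per-pixel read-noise variance in photon-equivalent units.
#'
#' @param activations data.frame from \code{simulateBlinking}.
#' @param field a \linkS4class{GroundTruthField}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param calibration a \linkS4class{CameraCalibration} matching the field.
#' @param shotNoise,readNoise logical switches; with both off the stack is
#'   the exact expectation (useful for flux-conservation checks).
#' @param channel channel label stored on the stack.
#' @return A \linkS4class{FrameStack}.
#' @export
renderStack <- function(activations, field, config, calibration,
                        shotNoise = TRUE, readNoise = TRUE,
                        channel = "A647") {
  n <- config@fieldSize
  if (!identical(dim(calibration@gain), c(n, n)))
    stop("calibration shape does not match the field size")
  set.seed(substreamSeed(config@seed, "render"))
  sigmaPx <- config@psfSigma / config@pixelSize
  halfw <- ceiling(6 * sigmaPx)
  em <- field@emitters
  dat <- array(0, dim = c(config@nFrames, n, n))
  mu0 <- matrix(config@bgPhotons, n, n)
  byFrame <- if (nrow(activations))
    split(activations, activations$frame) else list()
  for (f in seq_len(config@nFrames)) {
    mu <- mu0
    a <- byFrame[[as.character(f)]]
    if (!is.null(a) && nrow(a)) {
      for (k in seq_len(nrow(a))) {
        e <- a$emitter[k]
        cx <- em$x_nm[e] / config@pixelSize   # 0-based continuous col
        cy <- em$y_nm[e] / config@pixelSize   # 0-based continuous row
        jj <- max(0L, floor(cx) - halfw):min(n - 1L, ceiling(cx) + halfw)
        ii <- max(0L, floor(cy) - halfw):min(n - 1L, ceiling(cy) + halfw)
        if (!length(jj) || !length(ii)) next
        px <- intGaussPixels(jj, cx, sigmaPx)
        py <- intGaussPixels(ii, cy, sigmaPx)
        mu[ii + 1L, jj + 1L] <- mu[ii + 1L, jj + 1L] +
          a$photons[k] * (py %o% px)
      }
    }
    photons <- if (shotNoise)
      matrix(stats::rpois(n * n, mu), n, n) else mu
    adu <- calibration@gain * photons + calibration@offset
    if (readNoise)
      adu <- adu + calibration@gain *
        matrix(stats::rnorm(n * n, 0, sqrt(calibration@readnoiseVar)), n, n)
    dat[f, , ] <- adu
  }
  new("FrameStack", data = dat, pixelSize = config@pixelSize,
      channel = channel, calibrationRef = "simulated")
}

#' Simulate a two-channel bead fiducial field
#'
#' Reference bead positions are uniform over the field; moving-channel
#' positions are the true warp applied to the reference plus isotropic
#' Gaussian localization noise.
#'
#' @param nBeads number of beads (>= 6 for a degree-2 fit).
#' @param fieldNm length-2 numeric, field extent (x, y) in nm.
#' @param trueWarp a \linkS4class{PolynomialMapping} sending reference to
#'   moving coordinates.
#' @param locNoiseSd localization noise s.d. per coordinate (nm), added to
#'   the moving channel.
#' @param seed integer seed.
#' @return data.frame with columns ref_x_nm, ref_y_nm, mov_x_nm, mov_y_nm.
#' @export
simulateBeadField <- function(nBeads, fieldNm = c(1e4, 1e4),
                              trueWarp = identityMapping(),
                              locNoiseSd = 0, seed = 1L) {
  stopifnot(nBeads >= 1)
  set.seed(substreamSeed(seed, "beads"))
  ref <- data.frame(x = stats::runif(nBeads, 0, fieldNm[1L]),
                    y = stats::runif(nBeads, 0, fieldNm[2L]))
  mov <- applyMapping(trueWarp, ref)
  if (locNoiseSd > 0) {
    mov$x <- mov$x + stats::rnorm(nBeads, 0, locNoiseSd)
    mov$y <- mov$y + stats::rnorm(nBeads, 0, locNoiseSd)
  }
  data.frame(ref_x_nm = ref$x, ref_y_nm = ref$y,
             mov_x_nm = mov$x, mov_y_nm = mov$y)
}

#' Simulate a DNA fiber dataset
#'
#' Every fiber carries a first-label (IdU) tract drawn log-normally; with
#' probability \code{stallFraction} the fork is stalled (second-label length
#' exactly 0), otherwise the CldU tract is drawn from its own log-normal.
#' The per-fiber stall draw is recorded in \code{stalled_truth} so
#' downstream classification can be audited record-by-record.
#'
#' @param nFibers fibers per replicate.
#' @param stallFraction probability a fork is stalled, in [0, 1].
#' @param iduLen,clduLen list(meanlog, sdlog) of the log-normal tract-length
#'   distributions in micrometres. Defaults give a median ~8 um IdU and
#'   ~6 um CldU tract.
#' @param nReplicates independent replicates.
#' @param condition condition label attached to every fiber.
#' @param scheme labeling scheme: "restart", "protection" or "under_hu".
#' @param seed integer seed.
#' @return A \linkS4class{FiberDataset}.
#' @export
#' @examples
#' fd <- simulateFiberDataset(100L, 0.2, seed = 7L)
#' table(tracks(fd)$second_label_um == 0)
simulateFiberDataset <- function(nFibers, stallFraction,
                                 iduLen = list(meanlog = log(8), sdlog = 0.35),
                                 clduLen = list(meanlog = log(6), sdlog = 0.35),
                                 nReplicates = 3L, condition = "control",
                                 scheme = "restart", seed = 1L) {
  if (stallFraction < 0 || stallFraction > 1)
    stop("stallFraction must lie in [0, 1]")
  if (iduLen$sdlog < 0 || clduLen$sdlog < 0)
    stop("log-normal sdlog parameters must be non-negative")
  set.seed(substreamSeed(seed, paste0("fibers:", condition)))
  reps <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    idu <- stats::rlnorm(nFibers, iduLen$meanlog, iduLen$sdlog)
    stalled <- stats::runif(nFibers) < stallFraction
    cldu <- ifelse(stalled, 0,
                   stats::rlnorm(nFibers, clduLen$meanlog, clduLen$sdlog))
    reps[[r]] <- data.frame(
      fiber_id = sprintf("%s_r%d_f%d", condition, r, seq_len(nFibers)),
      condition = condition, replicate = r, scheme = scheme,
      first_label_um = idu, second_label_um = cldu,
      stalled_truth = stalled)
  }
  new("FiberDataset", tracks = do.call(rbind, reps), umToKb = 2.59,
      provenance = list(generator = "simulateFiberDataset",
                        nFibers = nFibers, stallFraction = stallFraction,
                        iduLen = iduLen, clduLen = clduLen,
                        nReplicates = nReplicates, condition = condition,
                        scheme = scheme, seed = seed))
}

#' Combine fiber datasets from several conditions
#'
#' @param ... \linkS4class{FiberDataset} objects sharing one scheme and
#'   conversion factor.
#' @return A single \linkS4class{FiberDataset}.
#' @export
combineFiberDatasets <- function(...) {
  ds <- list(...)
  stopifnot(length(ds) >= 1L)
  fac <- unique(vapply(ds, function(d) d@umToKb, numeric(1L)))
  if (length(fac) != 1L) stop("datasets disagree on the um-to-kb factor")
  new("FiberDataset", tracks = do.call(rbind, lapply(ds, tracks)),
      umToKb = fac, provenance = list(combined = lapply(ds, function(d) d@provenance)))
}
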