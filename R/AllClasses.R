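#' @import methods
NULL

#' Simulation configuration for synthetic SMLM experiments
#'
#' Holds every parameter of the synthetic nucleus / blinking-emitter /
#' camera model. Defaults encode the acquisition and geometry conditions of
#' the study being emulated: 33 Hz acquisition over 2000 frames, clustered
#' nascent-DNA (EdU) label with ~30 molecules per focus and ~40 foci per
#' nucleus, 1:1 fluorophore tagging.
#'
#' @slot fieldSize integer, field side length in pixels.
#' @slot pixelSize numeric, camera pixel size in the sample plane (nm).
#' @slot nClusters integer, number of label clusters ("foci") per nucleus.
#' @slot moleculesPerCluster integer, fluorophores per cluster.
#' @slot clusterSigma numeric, isotropic Gaussian cluster radius (s.d., nm).
#' @slot minClusterSep numeric, minimum centre-to-centre cluster distance
#'   (nm); 0 (default) places centres uniformly, a positive value enforces
#'   a hard-core ("well-separated") cluster layout.
#' @slot backgroundDensity numeric, unclustered monomer density (per um^2).
#' @slot nFrames integer, frames per acquisition.
#' @slot frameRateHz numeric, acquisition rate (metadata only).
#' @slot pOn numeric, per-frame activation probability of an off emitter.
#' @slot meanOnFrames numeric, mean consecutive on-frames once activated.
#' @slot photonsMean numeric, expected photons per on-frame.
#' @slot psfSigma numeric, Gaussian PSF s.d. (nm).
#' @slot bgPhotons numeric, uniform background photons per pixel per frame.
#' @slot seed integer, master seed expanded into per-stage substreams.
#' @export
setClass("SimulationConfig",
  representation(
    fieldSize = "integer", pixelSize = "numeric",
    nClusters = "integer", moleculesPerCluster = "integer",
    clusterSigma = "numeric", minClusterSep = "numeric",
    backgroundDensity = "numeric",
    nFrames = "integer", frameRateHz = "numeric",
    pOn = "numeric", meanOnFrames = "numeric",
    photonsMean = "numeric", psfSigma = "numeric",
    bgPhotons = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@fieldSize < 1L) msg <- c(msg, "fieldSize must be >= 1")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@psfSigma <= 0) msg <- c(msg, "psfSigma must be > 0")
  if (object@nClusters < 0L || object@moleculesPerCluster < 0L)
    msg <- c(msg, "cluster counts must be >= 0")
  if (object@clusterSigma < 0) msg <- c(msg, "clusterSigma must be >= 0")
  if (object@minClusterSep < 0) msg <- c(msg, "minClusterSep must be >= 0")
  if (object@backgroundDensity < 0) msg <- c(msg, "backgroundDensity must be >= 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@pOn < 0 || object@pOn > 1) msg <- c(msg, "pOn must lie in [0, 1]")
  if (object@meanOnFrames < 1) msg <- c(msg, "meanOnFrames must be >= 1")
  if (object@photonsMean < 0) msg <- c(msg, "photonsMean must be >= 0")
  if (object@bgPhotons < 0) msg <- c(msg, "bgPhotons must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-pixel sCMOS camera calibration
#'
#' Gain (ADU per photon), offset (ADU) and read-noise variance
#' (photon-equivalent units) maps, all sharing the frame shape. The
#' read-noise variance map captures the patterned, pixel-specific Gaussian
#' readout noise of sCMOS sensors that the localization likelihood must
#' account for.
#'
#' @slot gain matrix, ADU per photon, > 0 everywhere.
#' @slot offset matrix, ADU.
#' @slot readnoiseVar matrix, variance in photon-equivalent units, >= 0.
#' @export
setClass("CameraCalibration",
  representation(gain = "matrix", offset = "matrix", readnoiseVar = "matrix")
)

setValidity("CameraCalibration", function(object) {
  msg <- character()
  d <- dim(object@gain)
  if (!identical(d, dim(object@offset)) || !identical(d, dim(object@readnoiseVar)))
    msg <- c(msg, "gain, offset and readnoiseVar maps must share one shape")
  if (any(object@gain <= 0)) msg <- c(msg, "gain must be > 0 everywhere")
  if (any(object@readnoiseVar < 0)) msg <- c(msg, "readnoiseVar must be >= 0 everywhere")
  if (length(msg)) msg else TRUE
})

#' Multi-frame raw image stack
#'
#' Raw camera frames in ADU, the input to localization. Dimension order is
#' (frame, row, column).
#'
#' @slot data 3-D numeric array (frame, row, col) in ADU.
#' @slot pixelSize numeric, nm per pixel.
#' @slot channel character channel label.
#' @slot calibrationRef character identifier of the calibration used.
#' @export
setClass("FrameStack",
  representation(data = "array", pixelSize = "numeric",
                 channel = "character", calibrationRef = "character")
)

setValidity("FrameStack", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array (frame, row, col)")
  if (dim(object@data)[1L] < 1L) return("stack must contain at least one frame")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})

#' Nucleus mask
#'
#' Region of interest inside which emitters live and within which spatial
#' statistics are computed. Either an analytic ellipse (the default
#' synthetic nucleus) or an arbitrary raster mask.
#'
#' @slot type "ellipse" or "raster".
#' @slot center numeric length-2, ellipse centre (x, y) in nm.
#' @slot semiaxes numeric length-2, ellipse semi-axes (x, y) in nm.
#' @slot raster logical matrix (row = y, col = x) for raster masks.
#' @slot rasterPixel numeric, nm per raster pixel.
#' @slot origin numeric length-2, (x, y) nm of the centre of raster
#'   pixel [1, 1].
#' @export
setClass("NucleusMask",
  representation(type = "character", center = "numeric", semiaxes = "numeric",
                 raster = "matrix", rasterPixel = "numeric", origin = "numeric")
)

setValidity("NucleusMask", function(object) {
  if (!object@type %in% c("ellipse", "raster")) return("type must be 'ellipse' or 'raster'")
  if (object@type == "ellipse") {
    if (length(object@center) != 2L || length(object@semiaxes) != 2L)
      return("ellipse masks need length-2 center and semiaxes")
    if (any(object@semiaxes <= 0)) return("semiaxes must be > 0")
  } else {
    if (!is.logical(object@raster[1L])) return("raster must be a logical matrix")
    if (object@rasterPixel <= 0) return("rasterPixel must be > 0")
    if (!any(object@raster)) return("raster mask is empty")
  }
  TRUE
})

#' Ground-truth emitter field
#'
#' The exact emitter positions a synthetic nucleus was built from: clustered
#' fluorophores around focus centres plus a uniform monomer background, all
#' inside the nucleus mask. cluster id 0 marks background monomers.
#'
#' @slot mask NucleusMask the emitters live in.
#' @slot emitters data.frame with columns x_nm, y_nm, cluster.
#' @slot clusterCenters data.frame with columns x_nm, y_nm.
#' @slot config the SimulationConfig that produced the field.
#' @export
setClass("GroundTruthField",
  representation(mask = "NucleusMask", emitters = "data.frame",
                 clusterCenters = "data.frame", config = "SimulationConfig")
)

#' A set of single-molecule localizations
#'
#' Sub-pixel emitter coordinates with photon counts, fitted background,
#' CRLB precision and bookkeeping, as produced by \code{localizeStack} or
#' read from CSV. All records share one channel and pixel size. The
#' \code{space} slot names the coordinate frame; channel registration
#' rewrites it, and cross-channel analyses require matching spaces.
#'
#' @slot records data.frame with columns frame, channel, x_nm, y_nm,
#'   photons, background, sigma_nm, crlb_x_nm, crlb_y_nm, loglik, converged.
#' @slot pixelSize numeric, nm.
#' @slot source character, identifier of the originating stack.
#' @slot space character, coordinate-frame label.
#' @slot filterLog list of applied thresholds and per-reason rejection counts.
#' @export
setClass("LocalizationSet",
  representation(records = "data.frame", pixelSize = "numeric",
                 source = "character", space = "character", filterLog = "list")
)

setValidity("LocalizationSet", function(object) {
  need <- c("frame", "channel", "x_nm", "y_nm", "photons", "background",
            "sigma_nm", "crlb_x_nm", "crlb_y_nm", "loglik", "converged")
  miss <- setdiff(need, names(object@records))
  if (length(miss)) return(paste("records missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object@records) && length(unique(object@records$channel)) > 1L)
    return("all records must share one channel")
  TRUE
})

#' Second-degree polynomial channel mapping
#'
#' Maps moving-channel coordinates (nm) into the reference channel over the
#' monomial basis 1, x, y, x^2, xy, y^2 (degree 2; degree 1 uses the first
#' three monomials). Coefficients are reported in original nm units.
#'
#' @slot degree integer polynomial degree.
#' @slot coeffsX,coeffsY numeric coefficient vectors over the monomial basis.
#' @slot rmsResidual numeric, RMS 2-D residual distance (nm) on the fit points.
#' @slot nPoints integer, number of bead pairs used.
#' @export
setClass("PolynomialMapping",
  representation(degree = "integer", coeffsX = "numeric", coeffsY = "numeric",
                 rmsResidual = "numeric", nPoints = "integer")
)

setValidity("PolynomialMapping", function(object) {
  k <- (object@degree + 1L) * (object@degree + 2L) / 2L
  if (length(object@coeffsX) != k || length(object@coeffsY) != k)
    return(sprintf("degree %d needs %d coefficients per axis", object@degree, k))
  if (object@rmsResidual < 0) return("rmsResidual must be >= 0")
  TRUE
})

#' Radial pair-correlation profile
#'
#' g(r) (auto) or c(r) (cross) estimates over radial bins within a nucleus
#' mask, together with the average localization density used downstream to
#' derive cluster metrics. g = 1 everywhere for complete spatial randomness.
#'
#' @slot rCenters numeric, bin centres (nm), strictly increasing.
#' @slot g numeric, pair-correlation estimate per bin (dimensionless).
#' @slot binWidth,rMax numeric (nm).
#' @slot rho numeric, localization density in the mask (per um^2).
#' @slot nLocalizations integer (for cross profiles, the geometric-mean
#'   bookkeeping keeps the first set's count; both counts are in extra).
#' @slot maskArea numeric (um^2).
#' @slot kind "auto" or "cross".
#' @export
setClass("PairCorrelationProfile",
  representation(rCenters = "numeric", g = "numeric", binWidth = "numeric",
                 rMax = "numeric", rho = "numeric", nLocalizations = "integer",
                 maskArea = "numeric", kind = "character")
)

setValidity("PairCorrelationProfile", function(object) {
  msg <- character()
  if (any(object@g < 0)) msg <- c(msg, "g must be >= 0 in every bin")
  if (length(object@rCenters) > 1L && any(diff(object@rCenters) <= 0))
    msg <- c(msg, "rCenters must be strictly increasing")
  if (!object@kind %in% c("auto", "cross")) msg <- c(msg, "kind must be 'auto' or 'cross'")
  if (abs(object@rho - object@nLocalizations / object@maskArea) >
      1e-9 * max(1, object@rho))
    msg <- c(msg, "rho must equal nLocalizations / maskArea")
  if (length(msg)) msg else TRUE
})

#' Per-nucleus cluster metrics
#'
#' Average fluorophores per cluster (N_c), the relative total localization
#' count, and their ratio: the estimated number of label foci per nucleus.
#'
#' @slot moleculesPerCluster numeric, N_c >= 1.
#' @slot totalLocalizations integer.
#' @slot fociPerNucleus numeric, totalLocalizations / N_c.
#' @slot rho numeric, per um^2.
#' @slot integrationRMax numeric, upper radial limit actually integrated (nm).
#' @export
setClass("ClusterMetrics",
  representation(moleculesPerCluster = "numeric", totalLocalizations = "integer",
                 fociPerNucleus = "numeric", rho = "numeric",
                 integrationRMax = "numeric")
)

setValidity("ClusterMetrics", function(object) {
  msg <- character()
  if (object@moleculesPerCluster < 1) msg <- c(msg, "moleculesPerCluster must be >= 1")
  if (object@fociPerNucleus > object@totalLocalizations + 1e-9)
    msg <- c(msg, "fociPerNucleus cannot exceed totalLocalizations")
  prod <- object@fociPerNucleus * object@moleculesPerCluster
  if (abs(prod - object@totalLocalizations) > 1e-9 * max(1, object@totalLocalizations))
    msg <- c(msg, "foci x molecules-per-cluster must equal total localizations")
  if (length(msg)) msg else TRUE
})

#' DNA fiber dataset
#'
#' Per-fiber first-label (IdU) and second-label (CldU) segment lengths with
#' condition, replicate and labeling-scheme annotations.
#'
#' @slot tracks data.frame with columns fiber_id, condition, replicate,
#'   scheme, first_label_um, second_label_um (plus optional extras).
#' @slot umToKb numeric, kilobases per micrometre (default 2.59).
#' @slot provenance list describing the generator config or file source.
#' @export
setClass("FiberDataset",
  representation(tracks = "data.frame", umToKb = "numeric", provenance = "list")
)

setValidity("FiberDataset", function(object) {
  need <- c("fiber_id", "condition", "replicate", "scheme",
            "first_label_um", "second_label_um")
  miss <- setdiff(need, names(object@tracks))
  if (length(miss)) return(paste("tracks missing columns:", paste(miss, collapse = ", ")))
  tr <- object@tracks
  if (nrow(tr)) {
    if (any(!is.finite(tr$first_label_um)) || any(!is.finite(tr$second_label_um)))
      return("segment lengths must be finite")
    if (any(tr$first_label_um < 0) || any(tr$second_label_um < 0))
      return("segment lengths must be >= 0")
    if (length(unique(tr$scheme)) > 1L)
      return("scheme must be consistent within a dataset")
    if (!all(tr$scheme %in% c("restart", "protection", "under_hu")))
      return("scheme must be one of restart, protection, under_hu")
  }
  if (object@umToKb <= 0) return("umToKb must be > 0")
  TRUE
})

#' Replicate-level fiber summary
#'
#' Per-condition percent-stalled (mean +/- s.d. across replicates, Welch p
#' against the control) and pooled tract lengths (mean +/- s.e.m.,
#' Mann-Whitney p against the control).
#'
#' @slot percentStalled data.frame, one row per condition.
#' @slot tractLengths data.frame, one row per condition.
#' @slot control character, the designated control condition.
#' @slot notes character vector of replicate-minimum and degeneracy warnings.
#' @export
setClass("FiberSummary",
  representation(percentStalled = "data.frame", tractLengths = "data.frame",
                 control = "character", notes = "character")
)
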