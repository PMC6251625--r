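#' @include AllClasses.R
NULL

#' Accessors for forkfocus classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a forkfocus S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("locTable", function(object) standardGeneric("locTable"))
#' @rdname accessors
#' @export
setMethod("locTable", "LocalizationSet", function(object) object@records)

#' @rdname accessors
#' @export
setGeneric("filterLog", function(object) standardGeneric("filterLog"))
#' @rdname accessors
#' @export
setMethod("filterLog", "LocalizationSet", function(object) object@filterLog)

#' @rdname accessors
#' @export
setGeneric("coordSpace", function(object) standardGeneric("coordSpace"))
#' @rdname accessors
#' @export
setMethod("coordSpace", "LocalizationSet", function(object) object@space)

#' @rdname accessors
#' @export
setGeneric("stackData", function(object) standardGeneric("stackData"))
#' @rdname accessors
#' @export
setMethod("stackData", "FrameStack", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameStack", function(object) dim(object@data)[1L])

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "FrameStack", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "LocalizationSet", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "SimulationConfig", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("gainMap", function(object) standardGeneric("gainMap"))
#' @rdname accessors
#' @export
setMethod("gainMap", "CameraCalibration", function(object) object@gain)

#' @rdname accessors
#' @export
setGeneric("offsetMap", function(object) standardGeneric("offsetMap"))
#' @rdname accessors
#' @export
setMethod("offsetMap", "CameraCalibration", function(object) object@offset)

#' @rdname accessors
#' @export
setGeneric("readNoiseVarMap", function(object) standardGeneric("readNoiseVarMap"))
#' @rdname accessors
#' @export
setMethod("readNoiseVarMap", "CameraCalibration", function(object) object@readnoiseVar)

#' @rdname accessors
#' @export
setGeneric("emitters", function(object) standardGeneric("emitters"))
#' @rdname accessors
#' @export
setMethod("emitters", "GroundTruthField", function(object) object@emitters)

#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setMethod("clusterCenters", "GroundTruthField", function(object) object@clusterCenters)

#' @rdname accessors
#' @export
setGeneric("nucleusMask", function(object) standardGeneric("nucleusMask"))
#' @rdname accessors
#' @export
setMethod("nucleusMask", "GroundTruthField", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("profileTable", function(object) standardGeneric("profileTable"))
#' @rdname accessors
#' @export
setMethod("profileTable", "PairCorrelationProfile", function(object)
  data.frame(r_nm = object@rCenters, g = object@g, kind = object@kind))

#' @rdname accessors
#' @export
setGeneric("meanDensity", function(object) standardGeneric("meanDensity"))
#' @rdname accessors
#' @export
setMethod("meanDensity", "PairCorrelationProfile", function(object) object@rho)

#' @rdname accessors
#' @export
setGeneric("moleculesPerClusterValue", function(object)
  standardGeneric("moleculesPerClusterValue"))
#' @rdname accessors
#' @export
setMethod("moleculesPerClusterValue", "ClusterMetrics", function(object)
  object@moleculesPerCluster)

#' @rdname accessors
#' @export
setGeneric("fociPerNucleusValue", function(object)
  standardGeneric("fociPerNucleusValue"))
#' @rdname accessors
#' @export
setMethod("fociPerNucleusValue", "ClusterMetrics", function(object)
  object@fociPerNucleus)

#' @rdname accessors
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))
#' @rdname accessors
#' @export
setMethod("tracks", "FiberDataset", function(object) object@tracks)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@fieldSize, "px field,",
      object@pixelSize, "nm/px,", object@nFrames, "frames @",
      object@frameRateHz, "Hz\n")
  cat("  clusters:", object@nClusters, "x", object@moleculesPerCluster,
      "molecules, sigma", object@clusterSigma, "nm; background",
      object@backgroundDensity, "/um^2\n")
  cat("  blinking: pOn", object@pOn, ", mean on-frames", object@meanOnFrames,
      ",", object@photonsMean, "photons/frame; PSF sigma",
      object@psfSigma, "nm; seed", object@seed, "\n")
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FrameStack: %d frames of %dx%d px (%.0f nm/px), channel '%s'\n",
              d[1L], d[2L], d[3L], object@pixelSize, object@channel))
})

setMethod("show", "CameraCalibration", function(object) {
  d <- dim(object@gain)
  cat(sprintf("CameraCalibration: %dx%d px, mean gain %.3f ADU/photon, mean read-noise var %.3f\n",
              d[1L], d[2L], mean(object@gain), mean(object@readnoiseVar)))
})

setMethod("show", "GroundTruthField", function(object) {
  cat(sprintf("GroundTruthField: %d emitters (%d clustered, %d background), %d cluster centers\n",
              nrow(object@emitters), sum(object@emitters$cluster > 0),
              sum(object@emitters$cluster == 0), nrow(object@clusterCenters)))
})

setMethod("show", "LocalizationSet", function(object) {
  cat(sprintf("LocalizationSet: %d localizations, channel '%s', space '%s'\n",
              nrow(object@records),
              if (nrow(object@records)) as.character(object@records$channel[1L]) else "-",
              object@space))
  if (length(object@filterLog))
    cat("  filters:", paste(names(object@filterLog), unlist(lapply(object@filterLog, paste, collapse = "/")),
                            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PolynomialMapping", function(object) {
  cat(sprintf("PolynomialMapping: degree %d, %d points, rms residual %.3g nm\n",
              object@degree, object@nPoints, object@rmsResidual))
})

setMethod("show", "PairCorrelationProfile", function(object) {
  cat(sprintf("PairCorrelationProfile (%s): %d bins of %.0f nm to %.0f nm, rho %.2f /um^2, n = %d\n",
              object@kind, length(object@rCenters), object@binWidth,
              object@rMax, object@rho, object@nLocalizations))
})

setMethod("show", "ClusterMetrics", function(object) {
  cat(sprintf("ClusterMetrics: N_c %.2f molecules/cluster, %d localizations -> %.2f foci (integrated to %.0f nm)\n",
              object@moleculesPerCluster, object@totalLocalizations,
              object@fociPerNucleus, object@integrationRMax))
})

setMethod("show", "FiberDataset", function(object) {
  tr <- object@tracks
  cat(sprintf("FiberDataset: %d fibers, %d condition(s), scheme '%s', %.2f kb/um\n",
              nrow(tr), length(unique(tr$condition)),
              if (nrow(tr)) as.character(tr$scheme[1L]) else "-", object@umToKb))
})

setMethod("show", "FiberSummary", function(object) {
  cat("FiberSummary (control:", object@control, ")\n")
  cat("% stalled (mean +/- sd across replicates, Welch p vs control):\n")
  print(object@percentStalled, row.names = FALSE)
  cat("tract lengths kb (pooled, mean +/- sem, Mann-Whitney p vs control):\n")
  print(object@tractLengths, row.names = FALSE)
  if (length(object@notes)) cat("notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "NucleusMask", function(object) {
  if (object@type == "ellipse")
    cat(sprintf("NucleusMask (ellipse): center (%.0f, %.0f) nm, semiaxes (%.0f, %.0f) nm, area %.2f um^2\n",
                object@center[1L], object@center[2L], object@semiaxes[1L],
                object@semiaxes[2L], maskArea(object)))
  else
    cat(sprintf("NucleusMask (raster): %dx%d px at %.0f nm/px, area %.2f um^2\n",
                nrow(object@raster), ncol(object@raster), object@rasterPixel,
                maskArea(object)))
})
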