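#' @include AllClasses.R simulate.R localize.R register.R cluster.R fiber.R io.R
NULL

pipelineKnownKeys <- c("seed", "out", "stages", "simulate", "localize",
                       "register", "cluster", "fiber")

# Build a SimulationConfig from the simulate parameter block.
configFromBlock <- function(block, seed) {
  args <- block[intersect(names(block),
                          names(formals(simulationConfig)))]
  args$seed <- seed
  do.call(simulationConfig, args)
}

roundCoords <- function(df, cols, digits = 3L) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], digits)
  df
}

#' Run the full pipeline from a configuration
#'
#' Executes the requested stages in dependency order
#' (simulate -> localize -> register -> cluster; fiber independently),
#' writes every output file under \code{config$out}, and returns a manifest
#' listing parameters, per-stage record counts and MD5 checksums of every
#' output. Identical configuration + seed reproduces identical checksums;
#' coordinate outputs are rounded to 1e-3 nm before writing to keep the
#' checksums platform-stable.
#'
#' @param config a nested list, or the path to a YAML file with the same
#'   structure. Top-level keys: seed, out, stages (subset of
#'   "simulate", "localize", "register", "cluster", "fiber"), plus one
#'   parameter block per stage. Unknown top-level keys are rejected; input
#'   paths referenced by non-simulate stages are checked before anything
#'   runs.
#' @param manifestFile optional path for the manifest JSON (default
#'   \code{<out>/manifest.json}).
#' @return The manifest, invisibly as a list (also written to JSON).
#' @export
runPipeline <- function(config, manifestFile = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), pipelineKnownKeys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$out)) stop("config$out (output directory) is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages))
    stages <- intersect(c("simulate", "localize", "register", "cluster", "fiber"),
                        names(config))
  bad <- setdiff(stages, c("simulate", "localize", "register", "cluster", "fiber"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))

  # pre-flight: every externally referenced input must exist
  needFile <- c(if ("localize" %in% stages && !"simulate" %in% stages)
                  c(config$localize$stack, config$localize$calibration),
                if ("register" %in% stages && !"simulate" %in% stages)
                  config$register$beads,
                if ("cluster" %in% stages && !"localize" %in% stages &&
                    !"simulate" %in% stages)
                  c(config$cluster$localizations, config$cluster$mask),
                if ("fiber" %in% stages && !"simulate" %in% stages)
                  config$fiber$tracks)
  missing <- needFile[!vapply(needFile, file.exists, logical(1L))]
  if (length(missing))
    stop("missing input file(s): ", paste(unlist(missing), collapse = ", "))

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out, f)
  files <- character()
  counts <- list()
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  env <- new.env()
  if ("simulate" %in% stages) runStage("simulate", {
    blk <- if (is.null(config$simulate)) list() else config$simulate
    simCfg <- configFromBlock(blk, seed)
    env$simCfg <- simCfg
    env$calibration <- makeCameraCalibration(
      rep(simCfg@fieldSize, 2L),
      gainMean = blk$gainMean %||% 2,
      offsetMean = blk$offsetMean %||% 100,
      readnoiseVarRange = unlist(blk$readnoiseVarRange %||% c(1, 4)),
      seed = seed)
    env$gt <- simulateGroundTruth(simCfg)
    act <- simulateBlinking(env$gt, simCfg)
    env$stack <- renderStack(act, env$gt, simCfg, env$calibration)
    writeFrameStack(env$stack, out("stack.tif"))
    writeCalibration(env$calibration, out("calibration.tif"))
    utils::write.csv(roundCoords(emitters(env$gt), c("x_nm", "y_nm")),
                     out("ground_truth.csv"), row.names = FALSE)
    utils::write.csv(act, out("activations.csv"), row.names = FALSE)
    writeMask(nucleusMask(env$gt), out("mask.json"))
    files <- c(files, out(c("stack.tif", "stack.tif.json", "calibration.tif",
                             "calibration.tif.json", "ground_truth.csv",
                             "activations.csv", "mask.json")))
    counts$simulate <- list(emitters = nrow(emitters(env$gt)),
                             activations = nrow(act),
                             frames = nFrames(env$stack))
    if (!is.null(blk$beads)) {
      bd <- blk$beads
      env$beads <- simulateBeadField(
        nBeads = bd$nBeads %||% 20L,
        fieldNm = unlist(bd$fieldNm %||% c(1e4, 1e4)),
        trueWarp = if (!is.null(bd$warpCoeffsX))
          polynomialMapping(unlist(bd$warpCoeffsX), unlist(bd$warpCoeffsY))
        else identityMapping(),
        locNoiseSd = bd$locNoiseSd %||% 0, seed = seed)
      writeBeadPairs(roundCoords(env$beads, names(env$beads)), out("beads.csv"))
      files <- c(files, out("beads.csv"))
      counts$simulate$beads <- nrow(env$beads)
    }
    if (!is.null(blk$fibers)) {
      sets <- lapply(blk$fibers, function(fb)
        simulateFiberDataset(
          nFibers = fb$nFibers %||% 300L,
          stallFraction = fb$stallFraction %||% 0.2,
          nReplicates = fb$nReplicates %||% 3L,
          condition = fb$condition %||% "control",
          scheme = fb$scheme %||% "restart", seed = seed))
      env$fibers <- do.call(combineFiberDatasets, sets)
      writeFiberTracks(env$fibers, out("fibers.csv"))
      files <- c(files, out("fibers.csv"))
      counts$simulate$fibers <- nrow(tracks(env$fibers))
    }
  })

  if ("localize" %in% stages) runStage("localize", {
    blk <- if (is.null(config$localize)) list() else config$localize
    stack <- if (!is.null(env$stack)) env$stack else readFrameStack(blk$stack)
    calib <- if (!is.null(env$calibration)) env$calibration
             else readCalibration(blk$calibration)
    env$locs <- localizeStack(
      stack, calib,
      psfSigma = blk$psfSigma %||%
        (if (!is.null(env$simCfg)) env$simCfg@psfSigma else 100),
      boxWidth = blk$boxWidth %||% 3L,
      thresholdK = blk$thresholdK %||% 5,
      minSeparation = blk$minSeparation %||% 5,
      roiSize = blk$roiSize %||% 11L)
    locOut <- env$locs
    locOut@records <- roundCoords(locOut@records,
                                  c("x_nm", "y_nm", "crlb_x_nm", "crlb_y_nm"))
    writeLocalizations(locOut, out("localizations.csv"))
    files <- c(files, out("localizations.csv"))
    counts$localize <- c(list(localizations = nrow(locTable(env$locs))),
                          filterLog(env$locs)["rejected"])
  })

  if ("register" %in% stages) runStage("register", {
    blk <- if (is.null(config$register)) list() else config$register
    beads <- if (!is.null(env$beads)) env$beads else readBeadPairs(blk$beads)
    mp <- fitPolynomialMapping(beads[, c("ref_x_nm", "ref_y_nm")],
                               beads[, c("mov_x_nm", "mov_y_nm")],
                               degree = blk$degree %||% 2L)
    writeMapping(mp, out("mapping.json"))
    files <- c(files, out("mapping.json"))
    counts$register <- list(n_beads = mp@nPoints,
                             rms_residual_nm = mp@rmsResidual)
  })

  if ("cluster" %in% stages) runStage("cluster", {
    blk <- if (is.null(config$cluster)) list() else config$cluster
    mask <- if (!is.null(env$gt)) nucleusMask(env$gt) else readMask(blk$mask)
    locs <- if (!is.null(env$locs)) env$locs
            else readLocalizations(blk$localizations)
    pr <- autoPairCorrelation(locs, mask,
                              binWidth = blk$binWidth %||% 10,
                              rMax = blk$rMax %||% 1000)
    metrics <- fociPerNucleus(pr)
    utils::write.csv(transform(profileTable(pr), g = round(g, 6)),
                     out("profile.csv"), row.names = FALSE)
    utils::write.csv(data.frame(nucleus_id = "nucleus1",
                                condition = blk$condition %||% "control",
                                n_locs = metrics@totalLocalizations,
                                rho = round(metrics@rho, 6),
                                molecules_per_cluster =
                                  round(metrics@moleculesPerCluster, 6),
                                foci_per_nucleus =
                                  round(metrics@fociPerNucleus, 6)),
                     out("cluster_metrics.csv"), row.names = FALSE)
    files <- c(files, out(c("profile.csv", "cluster_metrics.csv")))
    counts$cluster <- list(localizations = metrics@totalLocalizations,
                            molecules_per_cluster = metrics@moleculesPerCluster,
                            foci_per_nucleus = metrics@fociPerNucleus)
  })

  if ("fiber" %in% stages) runStage("fiber", {
    blk <- if (is.null(config$fiber)) list() else config$fiber
    fd <- if (!is.null(env$fibers)) env$fibers else readFiberTracks(blk$tracks)
    control <- blk$control %||% "control"
    sm <- summarizeFibers(fd, control)
    utils::write.csv(sm@percentStalled, out("fiber_percent_stalled.csv"),
                     row.names = FALSE)
    utils::write.csv(sm@tractLengths, out("fiber_tract_lengths.csv"),
                     row.names = FALSE)
    files <- c(files, out(c("fiber_percent_stalled.csv",
                             "fiber_tract_lengths.csv")))
    counts$fiber <- list(tracks = nrow(tracks(fd)),
                          conditions = length(unique(tracks(fd)$condition)))
  })

  manifest <- list(
    seed = seed, stages = stages, parameters = config,
    versions = list(r = as.character(getRversion()),
                    forkfocus = as.character(utils::packageVersion("forkfocus"))),
    counts = counts,
    files = as.list(tools::md5sum(files)))
  if (is.null(manifestFile)) manifestFile <- out("manifest.json")
  jsonlite::write_json(manifest, manifestFile, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an on-disk demonstration fixture
#'
#' "tiny": one 64 x 64 px stack with 5 clusters over 200 frames plus a
#' 2-condition, 60-fibers-per-replicate fiber table; the whole pipeline
#' completes on it in well under a minute. "standard": the emulated-study
#' scale (40 clusters x 30 molecules, 2000 frames; 2 fiber conditions x 3
#' replicates x 300 fibers). The two sizes write into disjoint
#' subdirectories.
#'
#' @param dir base directory.
#' @param size "tiny" or "standard".
#' @param seed master seed.
#' @return list with the config (ready for \code{\link{runPipeline}}) and
#'   the fixture directory.
#' @export
makeDemoFixture <- function(dir, size = c("tiny", "standard"), seed = 1L) {
  size <- match.arg(size)
  fixDir <- file.path(dir, paste0("fixture_", size))
  dir.create(fixDir, recursive = TRUE, showWarnings = FALSE)
  simBlock <- if (size == "tiny") {
    list(fieldSize = 64L, nClusters = 5L, moleculesPerCluster = 20L,
         nFrames = 200L, pOn = 0.004,
         beads = list(nBeads = 20L, locNoiseSd = 2),
         fibers = list(list(condition = "control", stallFraction = 0.2,
                            nFibers = 60L, nReplicates = 3L),
                       list(condition = "treated", stallFraction = 0.5,
                            nFibers = 60L, nReplicates = 3L)))
  } else {
    list(fieldSize = 96L, nClusters = 40L, moleculesPerCluster = 30L,
         nFrames = 2000L, pOn = 0.002,
         beads = list(nBeads = 30L, locNoiseSd = 2),
         fibers = list(list(condition = "control", stallFraction = 0.2,
                            nFibers = 300L, nReplicates = 3L),
                       list(condition = "treated", stallFraction = 0.5,
                            nFibers = 300L, nReplicates = 3L)))
  }
  config <- list(seed = seed, out = file.path(fixDir, "run"),
                 stages = c("simulate", "localize", "register", "cluster",
                            "fiber"),
                 simulate = simBlock,
                 localize = list(),
                 register = list(degree = 2L),
                 cluster = list(binWidth = 10, rMax = 500),
                 fiber = list(control = "control"))
  yaml::write_yaml(config, file.path(fixDir, "config.yaml"))
  list(config = config, configFile = file.path(fixDir, "config.yaml"),
       dir = fixDir)
}
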