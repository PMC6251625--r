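#' @include AllClasses.R mle.R
NULL

#' Uniform box filter with reflective edges
#'
#' Each output pixel is the mean over the width x width neighbourhood;
#' edges are handled by mirror reflection (the edge row/column is
#' duplicated). Linear in the input and separable.
#'
#' @param frame 2-D numeric matrix.
#' @param width odd kernel width >= 3.
#' @return Filtered matrix, same shape.
#' @export
#' @examples
#' boxFilter(matrix(1, 8, 8), 3)  # stays 1 everywhere
boxFilter <- function(frame, width = 3L) {
  width <- as.integer(width)
  if (width %% 2L == 0L || width < 3L) stop("box width must be odd and >= 3")
  p <- (width - 1L) %/% 2L
  reflect <- function(m, pad) {
    rbind(m[pad:1, , drop = FALSE], m, m[nrow(m):(nrow(m) - pad + 1L), , drop = FALSE])
  }
  runmean <- function(m, w) {   # along rows (dimension 1)
    cs <- apply(m, 2L, cumsum)
    cs <- rbind(0, cs)
    (cs[(w + 1L):nrow(cs), , drop = FALSE] -
       cs[1L:(nrow(cs) - w), , drop = FALSE]) / w
  }
  out <- runmean(reflect(frame, p), width)
  out <- t(runmean(reflect(t(out), p), width))
  out
}

#' Detect candidate emitters in a filtered frame
#'
#' Returns pixels that are strict maxima of their 8-neighbourhood, exceed
#' the threshold, and are the largest response within \code{minSeparation}
#' pixels (ties broken towards the lowest (row, col)). Deterministic order:
#' row, then column.
#'
#' @param filtered 2-D matrix (typically a box-filtered frame).
#' @param threshold finite detection threshold on the filtered value.
#' @param minSeparation minimum centre-to-centre candidate distance (px).
#' @return data.frame with columns row, col (1-based) and peak_response;
#'   zero rows when nothing passes.
#' @export
detectCandidates <- function(filtered, threshold, minSeparation = 5) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  nr <- nrow(filtered); nc <- ncol(filtered)
  empty <- data.frame(row = integer(0), col = integer(0),
                      peak_response = numeric(0))
  if (nr < 3L || nc < 3L) return(empty)
  ctr <- filtered[2:(nr - 1L), 2:(nc - 1L)]
  isMax <- ctr > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- filtered[(2 + dr):(nr - 1L + dr), (2 + dc):(nc - 1L + dc)]
    # strict on forward neighbours, non-strict backwards would double-count
    # plateaus; require strictly greater than every neighbour
    isMax <- isMax & (ctr > nb)
  }
  w <- which(isMax, arr.ind = TRUE)
  if (!nrow(w)) return(empty)
  cand <- data.frame(row = w[, 1L] + 1L, col = w[, 2L] + 1L,
                     peak_response = ctr[w])
  # non-maximum suppression within minSeparation, strongest first,
  # ties towards lowest (row, col)
  ord <- order(-cand$peak_response, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    sel <- which(keep)
    d2 <- (cand$row[sel] - cand$row[i])^2 + (cand$col[sel] - cand$col[i])^2
    keep[i] <- all(d2 >= minSeparation^2)
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$row, cand$col), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Robust detection threshold for a filtered frame
#'
#' median + k * MAD of the filtered values; the default k = 5 rejects
#' virtually all background maxima while keeping single-fluorophore peaks.
#'
#' @param filtered filtered frame.
#' @param k MAD multiplier.
#' @return Numeric threshold.
#' @export
detectionThreshold <- function(filtered, k = 5) {
  stats::median(filtered) + k * stats::mad(filtered)
}

#' Cut fitting ROIs around candidates
#'
#' Converts each ROI to photon units, \code{(ADU - offset) / gain}, and
#' attaches the matching per-pixel read-noise variance patch. Candidates
#' closer than half the ROI size to the border are dropped and counted in
#' the log.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param calibration a \linkS4class{CameraCalibration} matching the stack.
#' @param candidates data.frame with columns frame, row, col (1-based).
#' @param roiSize odd ROI side length (default 11).
#' @return list with elements \code{patches} and \code{varPatches}
#'   (nROI x roiSize^2 matrices), \code{frame}, \code{row0}, \code{col0}
#'   (0-based field coordinates of each ROI's corner pixel) and
#'   \code{log} (candidate / kept / border-dropped counts).
#' @export
segmentRois <- function(stack, calibration, candidates, roiSize = 11L) {
  roiSize <- as.integer(roiSize)
  if (roiSize %% 2L == 0L) stop("roiSize must be odd")
  d <- dim(stack@data)
  if (!identical(dim(calibration@gain), d[2:3]))
    stop("calibration shape does not match the stack frames")
  h <- (roiSize - 1L) %/% 2L
  ok <- candidates$row > h & candidates$row <= d[2L] - h &
    candidates$col > h & candidates$col <= d[3L] - h
  kept <- candidates[ok, , drop = FALSE]
  n <- nrow(kept)
  patches <- matrix(0, n, roiSize^2)
  varPatches <- matrix(0, n, roiSize^2)
  for (i in seq_len(n)) {
    rr <- (kept$row[i] - h):(kept$row[i] + h)
    cc <- (kept$col[i] - h):(kept$col[i] + h)
    adu <- stack@data[kept$frame[i], rr, cc]
    patches[i, ] <- (adu - calibration@offset[rr, cc]) / calibration@gain[rr, cc]
    varPatches[i, ] <- calibration@readnoiseVar[rr, cc]
  }
  list(patches = patches, varPatches = varPatches,
       frame = kept$frame, row0 = kept$row - h - 1L, col0 = kept$col - h - 1L,
       log = list(candidates = nrow(candidates), kept = n,
                  border_dropped = nrow(candidates) - n))
}

#' Quality-filter a localization set
#'
#' Removes records failing any enabled threshold and logs per-reason
#' rejection counts. Idempotent: filtering an already-filtered set changes
#' nothing.
#'
#' @param set a \linkS4class{LocalizationSet}.
#' @param minPhotons minimum fitted photon count.
#' @param maxCrlb maximum lateral CRLB (nm) on either axis.
#' @param maxSigmaDeviation maximum relative deviation of the fitted sigma
#'   from the nominal sigma (only informative for free-sigma fits).
#' @param requireConvergence drop non-converged fits.
#' @param nominalSigma nm, reference for \code{maxSigmaDeviation}.
#' @return Filtered \linkS4class{LocalizationSet} with an updated filterLog.
#' @export
filterLocalizations <- function(set, minPhotons = 100, maxCrlb = 50,
                                maxSigmaDeviation = Inf,
                                requireConvergence = TRUE,
                                nominalSigma = NULL) {
  rec <- set@records
  n0 <- nrow(rec)
  rej <- c(photons = 0L, crlb = 0L, sigma = 0L, convergence = 0L)
  if (n0) {
    bad_p <- rec$photons < minPhotons
    bad_c <- !is.finite(rec$crlb_x_nm) | !is.finite(rec$crlb_y_nm) |
      rec$crlb_x_nm > maxCrlb | rec$crlb_y_nm > maxCrlb
    bad_s <- if (is.finite(maxSigmaDeviation) && !is.null(nominalSigma))
      abs(rec$sigma_nm - nominalSigma) / nominalSigma > maxSigmaDeviation
    else rep(FALSE, n0)
    bad_v <- if (requireConvergence) !rec$converged else rep(FALSE, n0)
    rej <- c(photons = sum(bad_p), crlb = sum(bad_c & !bad_p),
             sigma = sum(bad_s & !bad_p & !bad_c),
             convergence = sum(bad_v & !bad_p & !bad_c & !bad_s))
    rec <- rec[!(bad_p | bad_c | bad_s | bad_v), , drop = FALSE]
    rownames(rec) <- NULL
  }
  fl <- set@filterLog
  fl$thresholds <- list(minPhotons = minPhotons, maxCrlb = maxCrlb,
                        maxSigmaDeviation = maxSigmaDeviation,
                        requireConvergence = requireConvergence)
  fl$rejected <- as.list(rej)
  fl$input <- n0
  fl$output <- nrow(rec)
  initialize(set, records = rec, filterLog = fl)
}

#' Localize an entire stack
#'
#' The full detection-and-fitting chain over all frames: per-frame photon
#' conversion, box filtering, local-maxima candidate detection, ROI
#' segmentation, batch sCMOS-aware MLE fitting with CRLB precision, and
#' quality filtering. Per-frame results are independent; the output is
#' canonicalized by frame, then y, then x, so evaluation order never
#' changes the result.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param calibration matching \linkS4class{CameraCalibration}.
#' @param psfSigma nominal PSF sigma in nm.
#' @param boxWidth box-filter width (px).
#' @param thresholdK MAD multiplier for the detection threshold.
#' @param minSeparation candidate separation (px).
#' @param roiSize ROI side (px, odd).
#' @param model "fixed" or "free" sigma fitting.
#' @param filters list of arguments passed to
#'   \code{\link{filterLocalizations}}; \code{NULL} disables filtering.
#' @return A \linkS4class{LocalizationSet} in field nm coordinates (origin
#'   at the centre of pixel (0, 0), x along columns, y along rows).
#' @export
localizeStack <- function(stack, calibration, psfSigma = 100,
                          boxWidth = 3L, thresholdK = 5,
                          minSeparation = 5, roiSize = 11L,
                          model = "fixed", filters = list()) {
  nf <- dim(stack@data)[1L]
  candAll <- vector("list", nf)
  for (f in seq_len(nf)) {
    photons <- (stack@data[f, , ] - calibration@offset) / calibration@gain
    filt <- boxFilter(photons, boxWidth)
    thr <- detectionThreshold(filt, thresholdK)
    cand <- detectCandidates(filt, thr, minSeparation)
    if (nrow(cand)) cand$frame <- f
    candAll[[f]] <- cand
  }
  cand <- do.call(rbind, candAll[vapply(candAll, nrow, 1L) > 0])
  emptyRec <- data.frame(frame = integer(0), channel = character(0),
                         x_nm = numeric(0), y_nm = numeric(0),
                         photons = numeric(0), background = numeric(0),
                         sigma_nm = numeric(0), crlb_x_nm = numeric(0),
                         crlb_y_nm = numeric(0), loglik = numeric(0),
                         converged = logical(0))
  mkSet <- function(rec, log) new("LocalizationSet", records = rec,
                                  pixelSize = stack@pixelSize,
                                  source = stack@calibrationRef,
                                  space = paste0("camera:", stack@channel),
                                  filterLog = log)
  if (is.null(cand) || !nrow(cand))
    return(mkSet(emptyRec, list(candidates = 0L)))
  seg <- segmentRois(stack, calibration, cand, roiSize)
  if (!length(seg$frame)) return(mkSet(emptyRec, seg["log"]))
  sigmaPx <- psfSigma / stack@pixelSize
  fit <- fitPsfMleBatch(seg$patches, seg$varPatches, sigmaPx, model = model)
  cr <- crlbBatch(fit$x, fit$y, fit$N, fit$b, fit$sigma, seg$varPatches,
                  free = identical(model, "free"))
  px <- stack@pixelSize
  rec <- data.frame(
    frame = seg$frame, channel = stack@channel,
    x_nm = (seg$col0 + fit$x) * px, y_nm = (seg$row0 + fit$y) * px,
    photons = fit$N, background = fit$b, sigma_nm = fit$sigma * px,
    crlb_x_nm = cr$x * px, crlb_y_nm = cr$y * px,
    loglik = fit$loglik, converged = fit$converged & fit$valid)
  ext <- dim(stack@data)[2L] * px
  inField <- rec$x_nm > -px / 2 & rec$x_nm < ext & rec$y_nm > -px / 2 & rec$y_nm < ext
  rec <- rec[inField & rec$photons > 0, , drop = FALSE]
  rec <- rec[order(rec$frame, rec$y_nm, rec$x_nm), , drop = FALSE]
  rownames(rec) <- NULL
  out <- mkSet(rec, c(seg["log"], list(fitted = length(seg$frame))))
  if (is.null(filters)) out
  else do.call(filterLocalizations, c(list(out), filters,
                                      list(nominalSigma = psfSigma)))
}
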