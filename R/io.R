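#' @include AllClasses.R
NULL

# ---- on-disk formats --------------------------------------------------------
# Stacks: multi-page 16-bit TIFF (ADU rounded to integers, camera-style
# quantization) with a JSON sidecar (<file>.json) for pixel size, channel
# and the intensity scale. Calibration: 3-page 32-bit float TIFF
# (gain, offset, read-noise variance), each page normalized by a per-page
# scale recorded in the sidecar. Tables: plain CSV with documented headers,
# coordinates in nm, fiber lengths in um. Mappings and masks: JSON.

sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a frame stack as multi-page TIFF
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param path TIFF file path; a JSON sidecar \code{<path>.json} carries
#'   pixel size, channel and intensity scale.
#' @return \code{readFrameStack} returns a \linkS4class{FrameStack};
#'   \code{writeFrameStack} returns \code{path} invisibly.
#' @export
writeFrameStack <- function(stack, path) {
  d <- dim(stack@data)
  pages <- lapply(seq_len(d[1L]), function(f)
    pmin(pmax(round(stack@data[f, , ]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(kind = "FrameStack", scale = 65535,
                            pixel_size_nm = stack@pixelSize,
                            channel = stack@channel,
                            calibration_ref = stack@calibrationRef,
                            n_frames = d[1L]),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  d <- dim(pages[[1L]])
  dat <- array(0, dim = c(n, d[1L], d[2L]))
  for (f in seq_len(n)) dat[f, , ] <- pages[[f]] * meta$scale
  new("FrameStack", data = dat, pixelSize = meta$pixel_size_nm,
      channel = meta$channel, calibrationRef = meta$calibration_ref)
}

#' Write / read a camera calibration as a 3-page TIFF plus JSON sidecar
#'
#' Pages hold gain, offset and read-noise variance in that order, each
#' normalized by a per-page scale stored in the sidecar together with the
#' units.
#'
#' @param calibration a \linkS4class{CameraCalibration}.
#' @param path TIFF file path.
#' @return \code{readCalibration} returns a
#'   \linkS4class{CameraCalibration}; the writer returns \code{path}
#'   invisibly.
#' @export
writeCalibration <- function(calibration, path) {
  maps <- list(gain = calibration@gain, offset = calibration@offset,
               readnoise_var = calibration@readnoiseVar)
  scales <- vapply(maps, function(m) max(max(m), 1e-12), numeric(1L))
  pages <- mapply(function(m, s) m / s, maps, scales, SIMPLIFY = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(kind = "CameraCalibration",
                            pages = names(maps), scales = as.list(scales),
                            units = list(gain = "ADU/photon", offset = "ADU",
                                         readnoise_var = "photon^2")),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  sc <- unlist(meta$scales)
  new("CameraCalibration", gain = pages[[1L]] * sc[[1L]],
      offset = pages[[2L]] * sc[[2L]], readnoiseVar = pages[[3L]] * sc[[3L]])
}

#' Write / read a localization table as CSV
#'
#' Columns: frame, channel, x_nm, y_nm, photons, background, sigma_nm,
#' crlb_x_nm, crlb_y_nm, loglik, converged.
#'
#' @param set a \linkS4class{LocalizationSet}.
#' @param path CSV path.
#' @param pixelSize,channel metadata used when reading (channel defaults to
#'   the column value).
#' @return Reader returns a \linkS4class{LocalizationSet}.
#' @export
writeLocalizations <- function(set, path) {
  utils::write.csv(locTable(set), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path, pixelSize = NA_real_, channel = NULL) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(channel)) rec$channel <- channel
  new("LocalizationSet", records = rec, pixelSize = pixelSize,
      source = path,
      space = paste0("camera:", if (nrow(rec)) rec$channel[1L] else "unknown"),
      filterLog = list())
}

#' Write / read bead fiducial pairs as CSV
#'
#' Columns: ref_x_nm, ref_y_nm, mov_x_nm, mov_y_nm.
#'
#' @param pairs data.frame of paired bead coordinates.
#' @param path CSV path.
#' @export
writeBeadPairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBeadPairs
#' @export
readBeadPairs <- function(path) utils::read.csv(path)

#' Serialize / read a polynomial mapping as JSON
#'
#' @param mapping a \linkS4class{PolynomialMapping}.
#' @param path JSON path.
#' @export
writeMapping <- function(mapping, path) {
  jsonlite::write_json(list(kind = "PolynomialMapping",
                            degree = mapping@degree,
                            basis = names(mapping@coeffsX),
                            coeffs_x = as.list(mapping@coeffsX),
                            coeffs_y = as.list(mapping@coeffsY),
                            rms_residual_nm = mapping@rmsResidual,
                            n_points = mapping@nPoints),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMapping
#' @export
readMapping <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- polynomialMapping(unlist(j$coeffs_x), unlist(j$coeffs_y))
  m@rmsResidual <- j$rms_residual_nm
  m@nPoints <- as.integer(j$n_points)
  m
}

#' Write / read fiber tracks as CSV
#'
#' Columns: fiber_id, condition, replicate, scheme, first_label_um,
#' second_label_um (extra columns are preserved).
#'
#' @param dataset a \linkS4class{FiberDataset}.
#' @param path CSV path.
#' @param umToKb conversion factor used when reading.
#' @export
writeFiberTracks <- function(dataset, path) {
  utils::write.csv(tracks(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFiberTracks
#' @export
readFiberTracks <- function(path, umToKb = 2.59) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("FiberDataset", tracks = tr, umToKb = umToKb,
      provenance = list(file = path))
}

#' Serialize / read a nucleus mask
#'
#' Ellipse masks go to JSON; raster masks to a 1-bit-style TIFF with a JSON
#' sidecar.
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @param path file path (.json for ellipse, .tif for raster).
#' @export
writeMask <- function(mask, path) {
  if (mask@type == "ellipse") {
    jsonlite::write_json(list(kind = "NucleusMask", type = "ellipse",
                              center_nm = mask@center,
                              semiaxes_nm = mask@semiaxes),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    tiff::writeTIFF(mask@raster * 1, path, bits.per.sample = 8L,
                    compression = "none")
    jsonlite::write_json(list(kind = "NucleusMask", type = "raster",
                              raster_pixel_nm = mask@rasterPixel,
                              origin_nm = mask@origin),
                         sidecarPath(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  if (grepl("\\.json$", path)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    ellipseMask(j$center_nm, j$semiaxes_nm)
  } else {
    j <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
    r <- tiff::readTIFF(path)
    rasterMask(r > 0.5, j$raster_pixel_nm, j$origin_nm)
  }
}
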