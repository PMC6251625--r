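#' @include AllClasses.R
NULL

#' Derive a per-stage substream seed from a master seed
#'
#' One global seed deterministically expands into independent seeds for the
#' pipeline stages (ground truth, blinking, camera noise, beads, fibers, ...),
#' so that re-running one stage never perturbs another.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
#' @examples
#' substreamSeed(1L, "blinking")
substreamSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483645 + 1)
}

#' Construct an elliptical nucleus mask
#'
#' @param center numeric length-2, (x, y) centre in nm.
#' @param semiaxes numeric length-2, semi-axes in nm.
#' @return A \linkS4class{NucleusMask}.
#' @export
ellipseMask <- function(center, semiaxes) {
  new("NucleusMask", type = "ellipse", center = as.numeric(center),
      semiaxes = as.numeric(semiaxes),
      raster = matrix(TRUE, 1L, 1L), rasterPixel = 1, origin = c(0, 0))
}

#' Construct a raster nucleus mask
#'
#' @param raster logical matrix, rows index y and columns index x.
#' @param rasterPixel nm per raster pixel.
#' @param origin (x, y) nm of the centre of raster pixel [1, 1].
#' @return A \linkS4class{NucleusMask}.
#' @export
rasterMask <- function(raster, rasterPixel, origin = c(0, 0)) {
  new("NucleusMask", type = "raster", center = c(NA_real_, NA_real_),
      semiaxes = c(NA_real_, NA_real_), raster = raster,
      rasterPixel = as.numeric(rasterPixel), origin = as.numeric(origin))
}

#' Mask area in square micrometres
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @return Area in um^2.
#' @export
maskArea <- function(mask) {
  if (mask@type == "ellipse")
    pi * mask@semiaxes[1L] * mask@semiaxes[2L] / 1e6
  else
    sum(mask@raster) * mask@rasterPixel^2 / 1e6
}

#' Point-in-mask test (vectorized)
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @param x,y coordinates in nm.
#' @return Logical vector.
#' @export
maskContains <- function(mask, x, y) {
  if (mask@type == "ellipse") {
    ((x - mask@center[1L]) / mask@semiaxes[1L])^2 +
      ((y - mask@center[2L]) / mask@semiaxes[2L])^2 <= 1
  } else {
    ci <- round((x - mask@origin[1L]) / mask@rasterPixel) + 1
    ri <- round((y - mask@origin[2L]) / mask@rasterPixel) + 1
    ok <- ri >= 1 & ri <= nrow(mask@raster) & ci >= 1 & ci <= ncol(mask@raster)
    out <- logical(length(x))
    out[ok] <- mask@raster[cbind(ri[ok], ci[ok])]
    out
  }
}

#' Bounding box of a mask
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @return Numeric vector (xmin, xmax, ymin, ymax) in nm.
#' @export
maskBBox <- function(mask) {
  if (mask@type == "ellipse") {
    c(mask@center[1L] - mask@semiaxes[1L], mask@center[1L] + mask@semiaxes[1L],
      mask@center[2L] - mask@semiaxes[2L], mask@center[2L] + mask@semiaxes[2L])
  } else {
    rr <- range(which(rowSums(mask@raster) > 0))
    cc <- range(which(colSums(mask@raster) > 0))
    c(mask@origin[1L] + (cc[1L] - 1.5) * mask@rasterPixel,
      mask@origin[1L] + (cc[2L] - 0.5) * mask@rasterPixel,
      mask@origin[2L] + (rr[1L] - 1.5) * mask@rasterPixel,
      mask@origin[2L] + (rr[2L] - 0.5) * mask@rasterPixel)
  }
}

# Deterministic grid of reference points inside the mask, used for the
# annulus-area-inside-mask edge correction. Pitch is chosen so that roughly
# nTarget points fall inside; midpoint placement keeps the grid unbiased.
maskRefGrid <- function(mask, nTarget = 2048L) {
  bb <- maskBBox(mask)
  areaNm2 <- maskArea(mask) * 1e6
  pitch <- sqrt(areaNm2 / nTarget)
  xs <- seq(bb[1L] + pitch / 2, bb[2L], by = pitch)
  ys <- seq(bb[3L] + pitch / 2, bb[4L], by = pitch)
  g <- expand.grid(x = xs, y = ys)
  keep <- maskContains(mask, g$x, g$y)
  g[keep, , drop = FALSE]
}

# Hard-core point placement: uniform in the mask subject to a minimum
# pairwise separation, by sequential rejection. Errors out if the packing
# is infeasible at the requested density.
maskHardcore <- function(mask, n, minSep, maxTries = 200L) {
  pts <- maskUniform(mask, max(n, 1L))[0, , drop = FALSE]
  tries <- 0L
  while (nrow(pts) < n) {
    cand <- maskUniform(mask, 1L)
    ok <- !nrow(pts) ||
      min((pts$x_nm - cand$x_nm)^2 + (pts$y_nm - cand$y_nm)^2) >= minSep^2
    if (ok) {
      pts <- rbind(pts, cand)
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > maxTries * n)
        stop("cannot place ", n, " cluster centres at separation ", minSep,
             " nm in this mask")
    }
  }
  rownames(pts) <- NULL
  pts
}

# Uniform points inside the mask by rejection from the bounding box.
# Assumes the RNG state is already set by the caller.
maskUniform <- function(mask, n) {
  bb <- maskBBox(mask)
  out <- matrix(numeric(0), ncol = 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 64L)
    x <- stats::runif(m, bb[1L], bb[2L])
    y <- stats::runif(m, bb[3L], bb[4L])
    keep <- maskContains(mask, x, y)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  data.frame(x_nm = out[, 1L], y_nm = out[, 2L])
}
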