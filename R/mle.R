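#' @include AllClasses.R
NULL

# ---- sCMOS maximum-likelihood PSF fitting -----------------------------------
#
# Likelihood: pixel k with expected photons mu_k = N * PSF_k(x, y, sigma) + b
# and read-noise variance v_k (photon-equivalent units) is modeled as
# Poisson with effective rate mu_k + v_k observed as d_k + v_k -- the
# standard Poisson-plus-variance approximation that folds the Gaussian
# readout noise into the Poisson likelihood. Maximization is a damped
# per-parameter Newton ascent, fully vectorized across ROIs.

# Integrated-Gaussian factors and their x/sigma derivatives for 0-based
# pixel indices idx (vector) at continuous position c0 (vector, one per ROI).
# Returns n x length(idx) matrices.
psfFactors <- function(idx, c0, sigma) {
  u1 <- outer(-c0, idx + 0.5, `+`) / sigma   # (idx + 0.5 - c0)/sigma
  u2 <- outer(-c0, idx - 0.5, `+`) / sigma
  E <- stats::pnorm(u1) - stats::pnorm(u2)
  p1 <- stats::dnorm(u1); p2 <- stats::dnorm(u2)
  list(E = E,
       dE = (p2 - p1) / sigma,                       # dE/dc0
       d2E = (u2 * p2 - u1 * p1) / sigma^2,          # d2E/dc0^2
       dEs = (u2 * p2 - u1 * p1) / sigma)            # dE/dsigma
}

# Batch MLE over ROIs.
#   patches, varPatches: n x s^2 matrices (photon units), column-major over
#   an s x s patch (column index fastest is NOT assumed; we use our own
#   row/col index maps).
fitPsfMleBatch <- function(patches, varPatches, sigmaPx,
                           model = c("fixed", "free"),
                           init = NULL, maxIter = 50L, tol = 1e-6) {
  model <- match.arg(model)
  n <- nrow(patches)
  s2 <- ncol(patches)
  s <- as.integer(round(sqrt(s2)))
  stopifnot(s * s == s2, s %% 2L == 1L)
  cols0 <- rep(0:(s - 1L), each = s)    # pixel -> 0-based col, row-fastest
  rows0 <- rep(0:(s - 1L), times = s)
  colOf <- cols0 + 1L                   # index into s-length factor matrices
  rowOf <- rows0 + 1L

  D <- pmax(patches + varPatches, 0)
  v <- varPatches

  # initialization: border median as background, centroid of the excess
  border <- which(cols0 == 0L | cols0 == s - 1L | rows0 == 0L | rows0 == s - 1L)
  b <- pmax(apply(patches[, border, drop = FALSE], 1L, stats::median), 0.01)
  if (!is.null(init)) {
    x <- init$x; y <- init$y
    N <- init$N; b <- init$b
    sig <- if (!is.null(init$sigma)) init$sigma else rep(sigmaPx, n)
  } else {
    W <- pmax(patches - b, 0)
    sw <- rowSums(W)
    sw[sw <= 0] <- 1
    x <- as.numeric(W %*% cols0) / sw
    y <- as.numeric(W %*% rows0) / sw
    N <- pmax(rowSums(patches) - s2 * b, 10)
    sig <- rep(sigmaPx, n)
  }

  conv <- rep(FALSE, n)
  iterUsed <- rep(maxIter, n)
  c0 <- (s - 1) / 2
  for (it in seq_len(maxIter)) {
    fx <- psfFactors(0:(s - 1L), x, sig)
    fy <- psfFactors(0:(s - 1L), y, sig)
    PSF <- fx$E[, colOf, drop = FALSE] * fy$E[, rowOf, drop = FALSE]
    mu <- PSF * N + b
    denom <- pmax(mu + v, 1e-9)
    ratio <- D / denom - 1
    w2 <- D / denom^2

    newton <- function(dmu, d2mu) {
      L1 <- rowSums(dmu * ratio)
      L2 <- rowSums(d2mu * ratio - dmu * dmu * w2)
      step <- ifelse(L2 < 0, L1 / L2, -sign(L1) * 0.1)
      -step   # ascent increment to ADD
    }

    dmux <- (fx$dE[, colOf] * fy$E[, rowOf]) * N
    d2mux <- (fx$d2E[, colOf] * fy$E[, rowOf]) * N
    dx <- pmin(pmax(newton(dmux, d2mux), -1), 1)

    dmuy <- (fy$dE[, rowOf] * fx$E[, colOf]) * N
    d2muy <- (fy$d2E[, rowOf] * fx$E[, colOf]) * N
    dy <- pmin(pmax(newton(dmuy, d2muy), -1), 1)

    dN <- newton(PSF, 0 * PSF)
    db <- newton(matrix(1, n, s2), 0 * PSF)

    if (model == "free") {
      dmus <- (fx$dEs[, colOf] * fy$E[, rowOf] +
               fy$dEs[, rowOf] * fx$E[, colOf]) * N
      ds <- pmin(pmax(newton(dmus, 0 * PSF), -0.25 * sigmaPx), 0.25 * sigmaPx)
    } else ds <- numeric(n)

    xN <- pmin(pmax(x + dx, -1), s)
    yN <- pmin(pmax(y + dy, -1), s)
    NN <- pmax(N + dN, 1e-2)
    bN <- pmax(b + db, 0)
    sN <- if (model == "free") pmin(pmax(sig + ds, 0.3 * sigmaPx), 3 * sigmaPx) else sig

    rel <- pmax(abs(xN - x), abs(yN - y)) / s +
      abs(NN - N) / pmax(N, 1) + abs(bN - b) / pmax(b, 1) +
      abs(sN - sig) / sigmaPx
    justConv <- !conv & rel < tol
    iterUsed[justConv] <- it
    conv <- conv | justConv
    x <- xN; y <- yN; N <- NN; b <- bN; sig <- sN
    if (all(conv)) break
  }

  fx <- psfFactors(0:(s - 1L), x, sig)
  fy <- psfFactors(0:(s - 1L), y, sig)
  PSF <- fx$E[, colOf, drop = FALSE] * fy$E[, rowOf, drop = FALSE]
  mu <- PSF * N + b
  denom <- pmax(mu + v, 1e-9)
  loglik <- rowSums(D * log(denom) - denom)

  list(x = x, y = y, N = N, b = b, sigma = sig,
       loglik = loglik, converged = conv, iterations = iterUsed,
       valid = N > 0)
}

#' Fit one PSF by sCMOS-aware maximum likelihood
#'
#' Fits position, photon count, background (and optionally the PSF width)
#' of a single-emitter ROI by maximizing the Poisson-plus-read-noise
#' likelihood in which pixel k has effective Poisson rate
#' \code{mu_k + v_k}, \code{mu_k = N PSF_k(x, y, sigma) + b}. Iterative
#' Newton ascent from a centroid initialization; convergence when the
#' relative parameter step falls below \code{tol} (default 1e-6) or after
#' \code{maxIter} iterations.
#'
#' @param patch square odd-sided matrix of photon-converted pixel values.
#' @param varPatch matching per-pixel read-noise variances
#'   (photon-equivalent units).
#' @param sigmaPx PSF sigma in pixels (initial value; fixed unless
#'   \code{model = "free"}).
#' @param model "fixed" (sigma held at \code{sigmaPx}, the default) or
#'   "free" (sigma fitted).
#' @param init optional list(x, y, N, b, sigma) initialization in ROI pixel
#'   coordinates (0-based, origin at the centre of the corner pixel).
#' @param maxIter,tol iteration controls.
#' @return list with x, y (ROI pixel coordinates), N (photons),
#'   b (photons/pixel), sigma (px), loglik, converged, iterations, and the
#'   CRLB standard deviations crlb (named, pixel/photon units).
#' @export
#' @examples
#' s <- 11; sg <- 1.2
#' px <- outer(pnorm((0:(s-1)) + 0.5, 5.2, sg) - pnorm((0:(s-1)) - 0.5, 5.2, sg),
#'             pnorm((0:(s-1)) + 0.5, 4.8, sg) - pnorm((0:(s-1)) - 0.5, 4.8, sg))
#' roi <- 1000 * px + 5
#' f <- fitPsfMle(roi, matrix(0, s, s), sg)
#' c(f$x, f$y, f$N)
fitPsfMle <- function(patch, varPatch, sigmaPx, model = c("fixed", "free"),
                      init = NULL, maxIter = 50L, tol = 1e-6) {
  model <- match.arg(model)
  if (!all(dim(patch) == dim(varPatch))) stop("patch and varPatch shapes differ")
  s <- nrow(patch)
  if (s != ncol(patch) || s %% 2L == 0L) stop("patch must be square with odd side")
  if (max(patch) <= 0) stop("patch contains no positive signal")
  p <- matrix(as.numeric(patch), 1L)   # row-fastest flattening: patch[row, col]
  v <- matrix(as.numeric(varPatch), 1L)
  if (!is.null(init)) init <- lapply(init, as.numeric)
  fit <- fitPsfMleBatch(p, v, sigmaPx, model = model, init = init,
                        maxIter = maxIter, tol = tol)
  cr <- crlbBatch(fit$x, fit$y, fit$N, fit$b, fit$sigma, v,
                  free = identical(model, "free"))
  out <- lapply(fit, function(z) z[1L])
  out$crlb <- c(x = unname(cr$x[1L]), y = unname(cr$y[1L]),
                N = unname(cr$N[1L]), b = unname(cr$b[1L]))
  out
}

# Batch CRLB: sqrt of the diagonal of the inverse Fisher information of the
# same Poisson-plus-variance likelihood, evaluated at the given parameters.
# Returns pixel/photon units; NA where the Fisher matrix is singular.
crlbBatch <- function(x, y, N, b, sigma, varPatches, free = FALSE) {
  n <- length(x)
  s2 <- ncol(varPatches)
  s <- as.integer(round(sqrt(s2)))
  cols0 <- rep(0:(s - 1L), each = s)
  rows0 <- rep(0:(s - 1L), times = s)
  colOf <- cols0 + 1L; rowOf <- rows0 + 1L
  fx <- psfFactors(0:(s - 1L), x, sigma)
  fy <- psfFactors(0:(s - 1L), y, sigma)
  PSF <- fx$E[, colOf, drop = FALSE] * fy$E[, rowOf, drop = FALSE]
  mu <- PSF * N + b
  denom <- pmax(mu + varPatches, 1e-12)
  dlist <- list(
    x = (fx$dE[, colOf] * fy$E[, rowOf]) * N,
    y = (fy$dE[, rowOf] * fx$E[, colOf]) * N,
    N = PSF,
    b = matrix(1, n, s2))
  if (free)
    dlist$sigma <- (fx$dEs[, colOf] * fy$E[, rowOf] +
                    fy$dEs[, rowOf] * fx$E[, colOf]) * N
  k <- length(dlist)
  out <- matrix(NA_real_, n, k, dimnames = list(NULL, names(dlist)))
  singular <- logical(n)
  Iflat <- matrix(0, n, k * k)
  idx <- 1L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    Iflat[, idx] <- rowSums(dlist[[i]] * dlist[[j]] / denom)
    idx <- idx + 1L
  }
  for (r in seq_len(n)) {
    Im <- matrix(Iflat[r, ], k, k)
    d <- diag(Im)
    if (any(!is.finite(d)) || any(d <= 0)) { singular[r] <- TRUE; next }
    # Jacobi preconditioning: the b-information diverges as b, v -> 0, so
    # rescale to unit diagonal before inverting
    sc <- 1 / sqrt(d)
    inv <- tryCatch(solve(Im * (sc %o% sc)), error = function(e) NULL)
    if (is.null(inv) || any(diag(inv) <= 0)) singular[r] <- TRUE
    else out[r, ] <- sqrt(diag(inv)) * sc
  }
  list(x = out[, "x"], y = out[, "y"], N = out[, "N"], b = out[, "b"],
       sigma = if (free) out[, "sigma"] else NULL, singular = singular)
}

#' Cramer-Rao lower bound for a localization
#'
#' Precision bound of the sCMOS likelihood used in fitting, evaluated at
#' the supplied parameters: square roots of the diagonal of the inverse
#' Fisher information. Decreases with photon count N; increases with
#' background b and read-noise variance v.
#'
#' @param x,y emitter position in ROI pixel coordinates (0-based).
#' @param N photons, \code{b} background photons/pixel.
#' @param b background photons per pixel.
#' @param sigmaPx PSF sigma in pixels.
#' @param varPatch square matrix of per-pixel read-noise variances
#'   (photon-equivalent units) defining the ROI geometry.
#' @param free logical, include sigma in the parameter set.
#' @return Named numeric: crlb_x, crlb_y (pixels), crlb_N (photons),
#'   crlb_b (photons/pixel), plus crlb_sigma when \code{free}; all NA with
#'   attribute \code{singular = TRUE} if the Fisher matrix is singular.
#' @export
#' @examples
#' crlb(5, 5, 1000, 0, 1.2, matrix(0, 11, 11))
crlb <- function(x, y, N, b, sigmaPx, varPatch, free = FALSE) {
  v <- matrix(as.numeric(varPatch), 1L)
  cr <- crlbBatch(x, y, N, b, sigmaPx, v, free = free)
  out <- c(crlb_x = unname(cr$x[1L]), crlb_y = unname(cr$y[1L]),
           crlb_N = unname(cr$N[1L]), crlb_b = unname(cr$b[1L]))
  if (free) out <- c(out, crlb_sigma = unname(cr$sigma[1L]))
  attr(out, "singular") <- cr$singular[1L]
  out
}
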