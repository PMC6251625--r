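#' @include AllClasses.R
NULL

# Coerce a two-column coordinate object into a data.frame with columns x, y.
asXY <- function(p) {
  if (is.matrix(p)) p <- as.data.frame(p)
  nm <- names(p)
  if (all(c("x", "y") %in% nm)) return(data.frame(x = p$x, y = p$y))
  if (all(c("x_nm", "y_nm") %in% nm)) return(data.frame(x = p$x_nm, y = p$y_nm))
  if (ncol(p) >= 2L) return(data.frame(x = p[[1L]], y = p[[2L]]))
  stop("cannot interpret coordinates: need two columns (x, y)")
}

# Monomial basis {1, x, y} (degree 1) or {1, x, y, x^2, xy, y^2} (degree 2).
monomialBasis <- function(x, y, degree) {
  if (degree == 1L) cbind(1, x, y)
  else if (degree == 2L) cbind(1, x, y, x^2, x * y, y^2)
  else stop("only degrees 1 and 2 are supported")
}

monomialNames <- function(degree) {
  if (degree == 1L) c("1", "x", "y") else c("1", "x", "y", "x2", "xy", "y2")
}

#' Fit a polynomial mapping between two channels
#'
#' Least-squares fit, per axis, of a degree-1 or degree-2 polynomial over
#' the monomial basis sending moving-channel bead mass centres onto their
#' reference-channel partners. Coordinates are internally centred and
#' scaled to the bead bounding box for conditioning; the returned
#' coefficients are re-expanded into original nm units, so the fitted
#' mapping is identical either way.
#'
#' @param reference,moving paired coordinate lists (data.frame or matrix,
#'   two columns, nm), equal length.
#' @param degree polynomial degree (default 2; 6 coefficients per axis).
#' @return A \linkS4class{PolynomialMapping} sending moving onto reference.
#' @export
#' @examples
#' p <- data.frame(x = runif(20, 0, 1e4), y = runif(20, 0, 1e4))
#' m <- fitPolynomialMapping(p, p)
#' m@rmsResidual  # ~0
fitPolynomialMapping <- function(reference, moving, degree = 2L) {
  degree <- as.integer(degree)
  ref <- asXY(reference); mov <- asXY(moving)
  if (nrow(ref) != nrow(mov)) stop("reference and moving lists must be paired")
  k <- (degree + 1L) * (degree + 2L) / 2L
  if (nrow(mov) < k)
    stop(sprintf("need at least %d points for a degree-%d fit, got %d",
                 k, degree, nrow(mov)))
  cx <- mean(range(mov$x)); cy <- mean(range(mov$y))
  s <- max(diff(range(mov$x)), diff(range(mov$y))) / 2
  if (s <= 0) s <- 1
  u <- (mov$x - cx) / s; v <- (mov$y - cy) / s
  X <- monomialBasis(u, v, degree)
  qrX <- qr(X)
  if (qrX$rank < k)
    stop(sprintf("rank-deficient design (rank %d < %d): bead positions are degenerate (collinear or coincident)",
                 qrX$rank, k))
  ax <- qr.coef(qrX, ref$x)
  ay <- qr.coef(qrX, ref$y)
  bx <- rescaleCoeffs(ax, cx, cy, s, degree)
  by <- rescaleCoeffs(ay, cx, cy, s, degree)
  names(bx) <- names(by) <- monomialNames(degree)
  mapping <- new("PolynomialMapping", degree = degree, coeffsX = bx,
                 coeffsY = by, rmsResidual = 0, nPoints = nrow(mov))
  fit <- applyMapping(mapping, mov)
  mapping@rmsResidual <- sqrt(mean((ref$x - fit$x)^2 + (ref$y - fit$y)^2))
  mapping
}

# Re-expand coefficients fitted in centred/scaled coordinates
# u = (x - cx)/s, v = (y - cy)/s into the original monomial basis.
rescaleCoeffs <- function(a, cx, cy, s, degree) {
  if (degree == 1L) {
    c(a[1L] - a[2L] * cx / s - a[3L] * cy / s, a[2L] / s, a[3L] / s)
  } else {
    s2 <- s^2
    c(a[1L] - a[2L] * cx / s - a[3L] * cy / s +
        a[4L] * cx^2 / s2 + a[5L] * cx * cy / s2 + a[6L] * cy^2 / s2,
      a[2L] / s - 2 * a[4L] * cx / s2 - a[5L] * cy / s2,
      a[3L] / s - a[5L] * cx / s2 - 2 * a[6L] * cy / s2,
      a[4L] / s2, a[5L] / s2, a[6L] / s2)
  }
}

#' Identity polynomial mapping
#'
#' @param degree polynomial degree.
#' @return A \linkS4class{PolynomialMapping} that maps every point to itself.
#' @export
identityMapping <- function(degree = 2L) {
  degree <- as.integer(degree)
  k <- (degree + 1L) * (degree + 2L) / 2L
  cx <- numeric(k); cy <- numeric(k)
  cx[2L] <- 1; cy[3L] <- 1
  names(cx) <- names(cy) <- monomialNames(degree)
  new("PolynomialMapping", degree = degree, coeffsX = cx, coeffsY = cy,
      rmsResidual = 0, nPoints = 0L)
}

#' Construct a polynomial mapping from explicit coefficients
#'
#' @param coeffsX,coeffsY coefficient vectors over the monomial basis
#'   (length 3 for degree 1, 6 for degree 2) in original nm units.
#' @return A \linkS4class{PolynomialMapping}.
#' @export
polynomialMapping <- function(coeffsX, coeffsY) {
  k <- length(coeffsX)
  degree <- if (k == 3L) 1L else if (k == 6L) 2L else
    stop("coefficient vectors must have length 3 (degree 1) or 6 (degree 2)")
  cx <- as.numeric(coeffsX); cy <- as.numeric(coeffsY)
  names(cx) <- names(cy) <- monomialNames(degree)
  new("PolynomialMapping", degree = degree, coeffsX = cx, coeffsY = cy,
      rmsResidual = 0, nPoints = 0L)
}

#' Apply a polynomial mapping
#'
#' Evaluates both axis polynomials at each point. Length- and
#' order-preserving. Applied to a \linkS4class{LocalizationSet} it
#' transforms the coordinates and relabels the coordinate space.
#'
#' @param mapping a \linkS4class{PolynomialMapping}.
#' @param points coordinates (data.frame/matrix, nm) or a LocalizationSet.
#' @param space for LocalizationSet input, the new coordinate-space label.
#' @return Mapped coordinates of the same kind as the input.
#' @export
setGeneric("applyMapping", function(mapping, points, ...)
  standardGeneric("applyMapping"))

#' @rdname applyMapping
#' @export
setMethod("applyMapping", signature("PolynomialMapping", "data.frame"),
  function(mapping, points, ...) {
    p <- asXY(points)
    X <- monomialBasis(p$x, p$y, mapping@degree)
    data.frame(x = as.numeric(X %*% mapping@coeffsX),
               y = as.numeric(X %*% mapping@coeffsY))
  })

#' @rdname applyMapping
#' @export
setMethod("applyMapping", signature("PolynomialMapping", "matrix"),
  function(mapping, points, ...)
    applyMapping(mapping, as.data.frame(points)))

#' @rdname applyMapping
#' @export
setMethod("applyMapping", signature("PolynomialMapping", "LocalizationSet"),
  function(mapping, points, space = "reference", ...) {
    rec <- points@records
    if (nrow(rec)) {
      m <- applyMapping(mapping, data.frame(x = rec$x_nm, y = rec$y_nm))
      rec$x_nm <- m$x; rec$y_nm <- m$y
    }
    initialize(points, records = rec, space = space)
  })

#' Residual statistics of a mapping on holdout beads
#'
#' @param mapping a \linkS4class{PolynomialMapping}.
#' @param reference,moving paired holdout coordinates (nm) not used in the
#'   fit.
#' @return list with elements \code{rms} (RMS 2-D residual distance, nm),
#'   \code{max} (nm) and \code{residuals_nm} (per-point distances).
#' @export
mappingQuality <- function(mapping, reference, moving) {
  ref <- asXY(reference); mov <- asXY(moving)
  if (nrow(ref) == 0L) stop("holdout set is empty")
  if (nrow(ref) != nrow(mov)) stop("holdout lists must be paired")
  fit <- applyMapping(mapping, mov)
  d <- sqrt((ref$x - fit$x)^2 + (ref$y - fit$y)^2)
  list(rms = sqrt(mean(d^2)), max = max(d), residuals_nm = d)
}
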