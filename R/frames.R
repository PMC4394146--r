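# Surface navigation: local PCA coordinate frames and planar transect
# strips.  A frame at a surface point has tangent axes n1, n2 and outward
# normal n3 from the principal components of a spherical neighbourhood; a
# strip is the set of cloud points within |p' n2| <= delta of the cutting
# plane, optionally restricted to the half-plane p' n1 > 0.

#' Local PCA frame at a surface point
#'
#' Performs a principal component analysis of the cloud points within
#' \code{radius} of \code{center} (default 12 mm, which on the study-scale
#' data gives neighbourhoods of some tens of points).  The first two
#' components span the local tangent plane (n1, n2) and the third,
#' smallest-variance component is the surface normal n3, oriented away from
#' the cloud centroid (outward).  n1 is optionally oriented toward a
#' reference direction for reproducible transects; n2 completes a
#' right-handed system.
#'
#' @param cloud a \linkS4class{SurfacePointCloud}.
#' @param center numeric(3) frame origin (mm).
#' @param radius neighbourhood radius, mm (default 12).
#' @param refDirection optional numeric(3); n1 is flipped to have positive
#'   dot product with it.
#' @return a \linkS4class{LocalFrame} with origin \code{center}.
#' @export
localFrame <- function(cloud, center, radius = 12, refDirection = NULL) {
  P <- coords(cloud)
  d2 <- rowSums(sweep(P, 2, center)^2)
  nb <- P[d2 <= radius^2, , drop = FALSE]
  if (nrow(nb) < 10L)
    stop("only ", nrow(nb), " neighbours within radius ", radius,
         " mm; need at least 10")
  ev <- eigen(stats::cov(nb), symmetric = TRUE)
  n1 <- ev$vectors[, 1L]
  n3 <- ev$vectors[, 3L]
  outward <- center - colMeans(P)
  if (sum(n3 * outward) < 0) n3 <- -n3
  if (!is.null(refDirection) && sum(n1 * refDirection) < 0) n1 <- -n1
  # re-orthogonalise n1 against n3, then complete right-handed
  n1 <- .unit(n1 - sum(n1 * n3) * n3)
  n2 <- .cross(n3, n1)
  new("LocalFrame", origin = as.numeric(center),
      axes = unname(cbind(n1, n2, n3)))
}

#' Extract a planar transect strip
#'
#' Returns the cloud points satisfying \eqn{|p^T n_2| \le \delta} (and
#' \eqn{p^T n_1 > 0} for half-strips), coordinates taken relative to the
#' frame origin, together with in-plane coordinates (abscissa = projection
#' on n1, ordinate = projection on n3).  An empty strip is returned as a
#' 0-row strip with a warning, not an error.
#'
#' @param cloud a \linkS4class{SurfacePointCloud}.
#' @param frame a \linkS4class{LocalFrame} defining the cutting plane.
#' @param delta slab half-tolerance in mm (1 for torso transects, 1.2 for
#'   lip strips).
#' @param half logical; TRUE restricts to the half-plane pT n1 > 0.
#' @param maxAbscissa optional cap on the abscissa (transect length
#'   truncation, e.g. the 1.5x stopping rule).
#' @return a \linkS4class{TransectStrip}.
#' @export
planarStrip <- function(cloud, frame, delta, half = FALSE,
                        maxAbscissa = Inf) {
  if (delta < 0) stop("delta must be non-negative")
  P <- coords(cloud)
  rel <- sweep(P, 2, frame@origin)
  a <- drop(rel %*% frame@axes[, 1L])
  b <- drop(rel %*% frame@axes[, 2L])
  dd <- drop(rel %*% frame@axes[, 3L])
  keep <- abs(b) <= delta
  if (half) keep <- keep & a > 0
  keep <- keep & a <= maxAbscissa
  if (!any(keep))
    warning("empty transect strip (delta = ", delta, " mm)")
  new("TransectStrip", points = P[keep, , drop = FALSE], frame = frame,
      coords = cbind(abscissa = a[keep], ordinate = dd[keep]),
      delta = delta, half = half)
}

#' Rotate a frame about its normal axis
#'
#' Rotates n1 and n2 about n3 by \code{angle} radians (positive = clockwise
#' when viewed along -n3, the convention used to sweep radial transects);
#' the origin and n3 are unchanged and orthonormality is preserved.
#'
#' @param frame a \linkS4class{LocalFrame}.
#' @param angle rotation angle in radians.
#' @return the rotated \linkS4class{LocalFrame}.
#' @export
rotateFrame <- function(frame, angle) {
  n1 <- frame@axes[, 1L]; n2 <- frame@axes[, 2L]; n3 <- frame@axes[, 3L]
  ca <- cos(angle); sa <- sin(angle)
  m1 <- ca * n1 + sa * n2
  m2 <- -sa * n1 + ca * n2
  new("LocalFrame", origin = frame@origin,
      axes = unname(cbind(m1, m2, n3)))
}

# Map in-plane strip coordinates (abscissa, ordinate) back to 3D.
.stripTo3D <- function(strip, abscissa, ordinate) {
  fr <- strip@frame
  sweep(outer(abscissa, fr@axes[, 1L]) + outer(ordinate, fr@axes[, 3L]),
        2, fr@origin, "+")
}

#' Fit the in-plane principal curve of a transect strip
#'
#' Fits a 2D principal curve to the strip's (abscissa, ordinate)
#' coordinates, oriented so that arc length starts at the frame-origin end
#' (abscissa 0).
#'
#' @param strip a \linkS4class{TransectStrip}.
#' @param df smoothing degrees of freedom (6 for breast transects, 8 for
#'   lip transects).
#' @param ... further arguments to \code{\link{fitPrincipalCurve}}.
#' @return a 2D \linkS4class{PrincipalCurve}.
#' @export
stripCurve <- function(strip, df = 6, startNear = c(0, 0), ...) {
  fitPrincipalCurve(strip@coords, df = df, startNear = startNear, ...)
}
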