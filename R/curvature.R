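# Curvature of fitted curves.  Boundary evidence on transects comes from
# the signed planar curvature of the 2D principal curve; mouth corners come
# from the non-negative curvature of a 3D curve.

#' Signed planar curvature of a 2D principal curve
#'
#' Computes \eqn{\kappa(s) = (x'y'' - x''y') / (x'^2 + y'^2)^{3/2}} on the
#' curve's evaluation grid.  With the package's transect convention
#' (abscissa = in-plane direction n1, ordinate = surface-normal direction
#' n3), positive curvature means the curve bends toward +n3, i.e. toward the
#' outward surface normal: a convex mound gives negative curvature and the
#' crease where it joins the surrounding surface gives a positive maximum.
#' Grid points with vanishing speed (x'^2 + y'^2 < 1e-12) are masked as NA.
#'
#' @param curve a 2D \linkS4class{PrincipalCurve}.
#' @return a \linkS4class{CurvatureProfile}.
#' @export
planarCurvature <- function(curve) {
  stopifnot(is(curve, "PrincipalCurve"), curve@dim == 2L)
  s <- curve@sGrid
  d1 <- evalCurve(curve, s, deriv = 1L)
  d2 <- evalCurve(curve, s, deriv = 2L)
  sp2 <- d1[, 1]^2 + d1[, 2]^2
  k <- (d1[, 1] * d2[, 2] - d2[, 1] * d1[, 2]) / sp2^1.5
  k[sp2 < 1e-12] <- NA_real_
  new("CurvatureProfile", s = s, kappa = k)
}

#' Curvature of a 3D principal curve
#'
#' Computes the non-negative space curvature
#' \deqn{\kappa(s) = \frac{\sqrt{(x''y'-y''x')^2 + (x''z'-z''x')^2 +
#'   (y''z'-z''y')^2}}{(x'^2+y'^2+z'^2)^{3/2}}}
#' on the curve's evaluation grid.
#'
#' @param curve a 3D \linkS4class{PrincipalCurve}.
#' @return a \linkS4class{CurvatureProfile}.
#' @export
spaceCurvature <- function(curve) {
  stopifnot(is(curve, "PrincipalCurve"), curve@dim == 3L)
  s <- curve@sGrid
  d1 <- evalCurve(curve, s, deriv = 1L)
  d2 <- evalCurve(curve, s, deriv = 2L)
  sp2 <- rowSums(d1^2)
  num <- sqrt((d2[, 1] * d1[, 2] - d2[, 2] * d1[, 1])^2 +
              (d2[, 1] * d1[, 3] - d2[, 3] * d1[, 1])^2 +
              (d2[, 2] * d1[, 3] - d2[, 3] * d1[, 2])^2)
  k <- num / sp2^1.5
  k[sp2 < 1e-12] <- NA_real_
  new("CurvatureProfile", s = s, kappa = k)
}

#' Local maxima of a curvature profile
#'
#' Interior strict local maxima of kappa(s).  Plateaus report their first
#' grid index.  The outer \code{endMask} fraction of the arc length at each
#' end is excluded (spline derivatives are unreliable near the boundary).
#' When \code{requirePositive}, maxima with kappa <= 0 are dropped — on
#' transects these are bends away from the outward normal, which cannot be
#' junction creases.
#'
#' @param profile a \linkS4class{CurvatureProfile}.
#' @param requirePositive drop non-positive maxima (default TRUE).
#' @param endMask end fraction to exclude (default 0.02).
#' @return data.frame with columns \code{s}, \code{kappa} (possibly 0 rows).
#' @export
localCurvatureMaxima <- function(profile, requirePositive = TRUE,
                                 endMask = 0.02) {
  s <- profile@s
  k <- profile@kappa
  n <- length(s)
  if (n < 3L) stop("profile must have at least 3 points")
  lo <- s[1] + endMask * (s[n] - s[1])
  hi <- s[n] - endMask * (s[n] - s[1])
  hits <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (is.na(k[i])) { i <- i + 1L; next }
    # extend over a plateau of equal values
    j <- i
    while (j < n && !is.na(k[j + 1L]) && k[j + 1L] == k[i]) j <- j + 1L
    leftOk <- !is.na(k[i - 1L]) && k[i - 1L] < k[i]
    rightOk <- j < n && !is.na(k[j + 1L]) && k[j + 1L] < k[i]
    if (leftOk && rightOk) hits <- c(hits, i)   # first index of the plateau
    i <- j + 1L
  }
  if (length(hits)) hits <- hits[s[hits] >= lo & s[hits] <= hi]
  if (requirePositive && length(hits)) hits <- hits[k[hits] > 0]
  data.frame(s = s[hits], kappa = k[hits])
}

#' Export a curvature profile as CSV
#'
#' @param profile a \linkS4class{CurvatureProfile}.
#' @param path output path.
#' @export
writeCurvatureCSV <- function(profile, path) {
  utils::write.csv(data.frame(s = profile@s, kappa = profile@kappa),
                   path, row.names = FALSE)
  invisible(path)
}
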