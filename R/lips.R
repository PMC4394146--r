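# End-to-end lip boundary estimation: vertical strips across the mouth,
# change-point detection of the midline valley, curvature candidates for
# the upper and lower ridges, corner identification from midline curvature,
# and corner-constrained shape-penalized boundary fits.
#
# Curvature sign convention on vertical strips (ordinate = outward depth):
# the sharp valley where the closed lips meet bends toward the outward
# normal (kappa > 0), while the two boundary ridges are convex and bend
# away from it (kappa < 0).  Ridge candidates are therefore the positive
# local maxima of the negated curvature profile.

#' Fitted lip boundary curves
#'
#' Three 3D curves (upper, midline, lower) sharing the midline arc-length
#' parameterisation on [sL, sR], each stored as per-coordinate P-splines in
#' the global mouth frame; the upper and lower curves are equality-
#' constrained through both corners.
#'
#' @slot upper,midline,lower lists of 3 \linkS4class{PSplineModel} (frame
#'   coordinates against midline arc length).
#' @slot corners 2 x 3 corner coordinates (world, mm; rows L, R).
#' @slot sL,sR corner arc lengths on the midline curve.
#' @slot frameCenter,frameAxes the global mouth frame.
#' @export
setClass("LipCurves",
  representation(upper = "list", midline = "list", lower = "list",
                 corners = "matrix", sL = "numeric", sR = "numeric",
                 frameCenter = "numeric", frameAxes = "matrix"))

setMethod("show", "LipCurves", function(object) {
  cat(sprintf("LipCurves: corners at s = [%.1f, %.1f] mm (span %.1f mm)\n",
              object@sL, object@sR, object@sR - object@sL))
})

#' Global mouth frame and vertical strips
#'
#' Principal components of the mouth-region cloud define the global axis
#' system: n1 along the elongated (horizontal) mouth axis, n2 vertical,
#' n3 normal.  Vertical strips of slab tolerance \code{delta} are extracted
#' at \code{k} equally spaced offsets along n1.  Axis signs are fixed
#' against caller-supplied approximate up/right directions (the capture
#' protocol orients faces frontally; high accuracy is not needed).
#'
#' @param cloud mouth-region \linkS4class{SurfacePointCloud} (pre-cropped).
#' @param k number of strips (default 50).
#' @param delta slab half-tolerance, mm (default 1.2).
#' @param up,right approximate vertical and mouth-axis directions.
#' @return list with \code{strips} (list of \linkS4class{TransectStrip}),
#'   \code{center} and \code{axes} (columns n1, n2, n3).
#' @export
verticalStrips <- function(cloud, k = 50L, delta = 1.2,
                           up = c(0, 1, 0), right = c(1, 0, 0)) {
  P <- coords(cloud)
  ctr <- colMeans(P)
  ev <- eigen(stats::cov(P), symmetric = TRUE)
  n1 <- ev$vectors[, 1L]; n2 <- ev$vectors[, 2L]; n3 <- ev$vectors[, 3L]
  if (sum(n1 * right) < 0) n1 <- -n1
  if (sum(n2 * up) < 0) n2 <- -n2
  if (nrow(cloud@normals) == nrow(P)) {
    if (sum(cloud@normals %*% n3) < 0) n3 <- -n3
  } else {
    mid <- which.min(rowSums(sweep(P, 2, ctr)^2))
    if (sum((P[mid, ] - ctr) * n3) < 0) n3 <- -n3
  }
  a <- drop(sweep(P, 2, ctr) %*% n1)
  offs <- seq(min(a) + delta, max(a) - delta, length.out = k)
  strips <- lapply(offs, function(o) {
    fr <- new("LocalFrame", origin = ctr + o * n1,
              axes = unname(cbind(n2, n1, n3)))  # slab n1, abscissa vertical
    suppressWarnings(planarStrip(cloud, fr, delta, half = FALSE))
  })
  list(strips = strips, center = ctr, axes = cbind(n1, n2, n3),
       offsets = offs)
}

#' Detect lip boundary points on one vertical strip
#'
#' Fits the strip's vertical principal curve (df 8 to accommodate the two
#' ridges and intervening valley), scans the depth signal for a sharp
#' first-derivative change, and declares a midline point only when
#' |T| exceeds \code{threshold} (default 5).  Where a midline is detected,
#' the positive local maxima of the negated curvature profile above and
#' below the midline arc length become upper and lower ridge candidates.
#'
#' @param strip a vertical \linkS4class{TransectStrip}.
#' @param df smoothing df for the vertical curve and the one-sided scans
#'   (default 8).
#' @param threshold midline evidence threshold on |T| (default 5).
#' @param gridMax scan grid size cap.
#' @return list with \code{midline} (NULL or list(s, T, point)),
#'   \code{upper}/\code{lower} candidate data.frames (s, kappa, x, y, z),
#'   the fitted \code{curve} and \code{statistic} (max |T|).  Candidates
#'   are empty whenever the midline is absent.
#' @export
detectLipPoints <- function(strip, df = 8, threshold = 5, gridMax = 200L) {
  none <- data.frame(s = numeric(), kappa = numeric(), x = numeric(),
                     y = numeric(), z = numeric())
  out <- list(midline = NULL, upper = none, lower = none, curve = NULL,
              statistic = NA_real_)
  if (nrow(strip@points) < max(df + 2, 20)) return(out)
  crv <- tryCatch(
    stripCurve(strip, df = df, startNear = c(min(strip@coords[, 1]), 0)),
    error = function(e) NULL)
  if (is.null(crv)) return(out)
  out$curve <- crv
  pr <- projectToCurve(crv, strip@coords, refine = FALSE)
  scan <- tryCatch(
    scanDerivativeChange(pr$s, strip@coords[, 2], df = df,
                         gridMax = gridMax),
    error = function(e) NULL)
  if (is.null(scan)) return(out)
  ok <- is.finite(scan@T)
  out$statistic <- if (any(ok)) max(abs(scan@T[ok])) else NA_real_
  feat <- detectFeature(scan, threshold, sign = "positive")
  if (is.null(feat)) return(out)
  fp <- evalCurve(crv, feat$s)
  mp <- .stripTo3D(strip, fp[, 1], fp[, 2])
  out$midline <- list(s = feat$s, T = feat$T, point = mp[1, ])
  prof <- planarCurvature(crv)
  ridge <- new("CurvatureProfile", s = prof@s, kappa = -prof@kappa)
  mx <- localCurvatureMaxima(ridge, requirePositive = TRUE)
  if (nrow(mx)) {
    fp <- evalCurve(crv, mx$s)
    p3 <- .stripTo3D(strip, fp[, 1], fp[, 2])
    cand <- data.frame(s = mx$s, kappa = mx$kappa,
                       x = p3[, 1], y = p3[, 2], z = p3[, 3])
    out$upper <- cand[cand$s > feat$s, , drop = FALSE]
    out$lower <- cand[cand$s < feat$s, , drop = FALSE]
  }
  out
}

#' Resolve multiple ridge candidates per strip
#'
#' A preliminary 3D principal curve is fitted through the strips that
#' produced exactly one candidate for the given boundary.  For each
#' multi-candidate strip, the crossing of the preliminary curve with the
#' strip plane is projected onto the strip's vertical principal curve, and
#' the candidate whose arc length is closest to that crossing is kept
#' (ties: smaller arc length).  Single candidates pass through unchanged.
#'
#' @param results list of per-strip results from
#'   \code{\link{detectLipPoints}}.
#' @param which "upper" or "lower".
#' @param df smoothing df of the preliminary curve (default 8).
#' @return list of one-row (or empty) candidate data.frames, one per strip.
#' @export
resolveMultipleCandidates <- function(results, which = c("upper", "lower"),
                                      df = 8) {
  which <- match.arg(which)
  cands <- lapply(results, `[[`, which)
  ns <- vapply(cands, nrow, 0L)
  single <- which(ns == 1L)
  if (!any(ns > 1L)) return(cands)
  prelimPts <- if (length(single) >= df + 2) {
    do.call(rbind, lapply(cands[single], function(d)
      as.matrix(d[, c("x", "y", "z")])))
  } else {
    # no (or too few) unambiguous strips: seed the preliminary curve with
    # the strongest candidate per strip instead
    do.call(rbind, lapply(cands[ns > 0L], function(d)
      as.matrix(d[which.max(d$kappa), c("x", "y", "z")])))
  }
  if (nrow(prelimPts) < df + 2)
    stop("not enough candidate strips to build a preliminary curve")
  prelim <- fitPrincipalCurve(prelimPts, df = df)
  out <- cands
  for (i in which(ns > 1L)) {
    if (is.null(results[[i]]$curve)) next
    cd <- cands[[i]]
    sPrelim <- .prelimCrossingArc(prelim, results[[i]])
    if (is.na(sPrelim)) next
    dist <- abs(cd$s - sPrelim)
    keep <- which(dist == min(dist))
    keep <- keep[which.min(cd$s[keep])]
    out[[i]] <- cd[keep, , drop = FALSE]
  }
  out
}

# arc length (on the strip's vertical curve) where the preliminary 3D curve
# crosses the strip plane; NA if the crossing is far from the strip
.prelimCrossingArc <- function(prelim, result) {
  crv <- result$curve
  strip <- result$strip
  if (is.null(strip)) return(NA_real_)
  fr <- strip@frame
  slab <- drop(sweep(prelim@grid, 2, fr@origin) %*% fr@axes[, 2L])
  i <- which.min(abs(slab))
  rel <- prelim@grid[i, ] - fr@origin
  p2 <- c(sum(rel * fr@axes[, 1L]), sum(rel * fr@axes[, 3L]))
  projectToCurve(crv, p2, refine = FALSE)$s
}

#' Identify the mouth corners from midline curvature
#'
#' Fits a 3D principal curve to the detected midline points, computes its
#' space curvature and takes the first and last local maxima as the
#' corners, after masking 2\% end regions and requiring the maxima to
#' exceed the 75th percentile of the profile (a floor against micro-maxima
#' from noise).
#'
#' @param midlinePoints m x 3 matrix of detected midline points.
#' @param df smoothing df of the midline curve (default 15; enough to bend
#'   sharply at the corners).
#' @param floorQuantile curvature floor quantile (default 0.75).
#' @param endMask fraction of arc length masked at each end of the profile
#'   (default 0.05: the fitted curve's end regions carry leverage-driven
#'   curvature wiggles that can rival the corner bends).
#' @return list with \code{corners} (2 x 3, rows L/R by arc order),
#'   \code{sL}, \code{sR} and the fitted midline \code{curve}.
#' @export
findCorners <- function(midlinePoints, df = 15, floorQuantile = 0.75,
                        endMask = 0.05) {
  midlinePoints <- as.matrix(midlinePoints)
  if (nrow(midlinePoints) < 10L)
    stop("need at least 10 midline points, have ", nrow(midlinePoints))
  df <- min(df, nrow(midlinePoints) - 2L)
  crv <- fitPrincipalCurve(midlinePoints, df = df)
  prof <- spaceCurvature(crv)
  mx <- localCurvatureMaxima(prof, requirePositive = TRUE,
                             endMask = endMask)
  floor <- quantile(prof@kappa[is.finite(prof@kappa)], floorQuantile)
  mx <- mx[mx$kappa >= floor, , drop = FALSE]
  if (nrow(mx) < 2L)
    stop("fewer than 2 curvature maxima on the midline; corners not found")
  sL <- mx$s[1L]; sR <- mx$s[nrow(mx)]
  corners <- evalCurve(crv, c(sL, sR))
  rownames(corners) <- c("L", "R")
  list(corners = corners, sL = sL, sR = sR, curve = crv)
}

#' Fit corner-constrained lip boundary curves
#'
#' All three curves share the midline arc-length parameterisation:
#' candidates are assigned s by projection onto the midline curve and
#' points beyond the corners are discarded.  Each coordinate (in the global
#' mouth frame) is fitted against s at \code{df} degrees of freedom
#' (default 25, to allow good estimation of the central upper lip where a
#' notch may be present) and constrained through the corners; the vertical
#' coordinate of the upper and lower curves additionally carries the
#' monotonicity and second-derivative shape penalties with
#' kappa = \code{kappaFactor} * lambda.
#'
#' @param results per-strip results (\code{\link{detectLipPoints}}).
#' @param upperCands,lowerCands resolved candidate lists
#'   (\code{\link{resolveMultipleCandidates}}).
#' @param cornerInfo output of \code{\link{findCorners}}.
#' @param frame list with \code{center}, \code{axes} from
#'   \code{\link{verticalStrips}}.
#' @param df smoothing df (default 25).
#' @param nbasis basis size (default 30).
#' @param kappaFactor shape-penalty multiple of lambda (default 100).
#' @return a \linkS4class{LipCurves}.
#' @export
fitLipBoundaries <- function(results, upperCands, lowerCands, cornerInfo,
                             frame, df = 25, nbasis = 30L,
                             kappaFactor = 100) {
  mcrv <- cornerInfo$curve
  sL <- cornerInfo$sL; sR <- cornerInfo$sR
  ctr <- frame$center; Ax <- frame$axes
  toFrame <- function(P) sweep(as.matrix(P), 2, ctr) %*% Ax
  fromFrame <- function(Q) sweep(Q %*% t(Ax), 2, ctr, "+")
  cornersF <- toFrame(cornerInfo$corners)

  fitOne <- function(P, shapes) {
    pr <- projectToCurve(mcrv, P, refine = FALSE)
    keep <- pr$s >= sL & pr$s <= sR
    s <- pr$s[keep]
    Q <- toFrame(P[keep, , drop = FALSE])
    if (length(s) < 10L)
      stop("fewer than 10 candidates between the corners")
    dfUse <- min(df, length(s) - 2L)
    lapply(1:3, function(j) {
      sh <- if (j == 2L) shapes else shapeSpec()  # vertical is coord 2
      fitShapeConstrained(s, Q[, j], nbasis = nbasis, df = dfUse,
                          at = c(sL, sR),
                          values = c(cornersF[1, j], cornersF[2, j]),
                          shapes = sh, kappaFactor = kappaFactor,
                          srange = c(sL, sR))
    })
  }

  upPts <- do.call(rbind, lapply(upperCands, function(d)
    if (nrow(d)) as.matrix(d[, c("x", "y", "z")]) else NULL))
  loPts <- do.call(rbind, lapply(lowerCands, function(d)
    if (nrow(d)) as.matrix(d[, c("x", "y", "z")]) else NULL))
  midPts <- do.call(rbind, lapply(results, function(r)
    if (!is.null(r$midline)) matrix(r$midline$point, 1) else NULL))

  upper <- fitOne(upPts, upperLipShape())
  lower <- fitOne(loPts, lowerLipShape())
  midline <- fitOne(midPts, shapeSpec())
  new("LipCurves", upper = upper, midline = midline, lower = lower,
      corners = cornerInfo$corners, sL = sL, sR = sR,
      frameCenter = ctr, frameAxes = Ax)
}

#' Evaluate a fitted lip curve
#'
#' @param fit a \linkS4class{LipCurves}.
#' @param which "upper", "midline" or "lower".
#' @param s midline arc lengths in [sL, sR]; default 51 equally spaced
#'   points (the curve-agreement evaluation protocol).
#' @return length(s) x 3 matrix of world coordinates.
#' @export
evalLipCurve <- function(fit, which = c("upper", "midline", "lower"),
                         s = NULL) {
  which <- match.arg(which)
  if (is.null(s)) s <- seq(fit@sL, fit@sR, length.out = 51L)
  models <- slot(fit, which)
  Q <- vapply(models, psplineEval, numeric(length(s)), s = s)
  Q <- matrix(Q, nrow = length(s))
  sweep(Q %*% t(fit@frameAxes), 2, fit@frameCenter, "+")
}

#' Curve agreement with a reference polyline
#'
#' The root of the average squared distance between a fitted lip curve,
#' evaluated at 51 equally spaced arc lengths, and a dense reference
#' polyline, overall and decomposed into x/y/z components (nearest-vertex
#' differences).
#'
#' @param fit a \linkS4class{LipCurves}.
#' @param which curve name.
#' @param reference m x 3 reference polyline.
#' @param n number of evaluation points (default 51).
#' @return named numeric: overall, x, y, z (mm).
#' @export
lipCurveAgreement <- function(fit, which, reference, n = 51L) {
  P <- evalLipCurve(fit, which,
                    s = seq(fit@sL, fit@sR, length.out = n))
  reference <- as.matrix(reference)
  d <- polylineDistance(P, reference)
  nearest <- vapply(seq_len(nrow(P)), function(i)
    which.min(colSums((t(reference) - P[i, ])^2)), 0L)
  diff <- P - reference[nearest, , drop = FALSE]
  c(overall = sqrt(mean(d^2)),
    x = sqrt(mean(diff[, 1]^2)),
    y = sqrt(mean(diff[, 2]^2)),
    z = sqrt(mean(diff[, 3]^2)))
}

#' Run the lip boundary pipeline
#'
#' Vertical strips, per-strip midline detection and ridge candidates,
#' corner identification from midline curvature, candidate resolution
#' against preliminary curves, and corner-constrained shape-penalized
#' boundary fits.
#'
#' @param cloud mouth-region \linkS4class{SurfacePointCloud}.
#' @param k number of vertical strips (default 50).
#' @param delta slab half-tolerance (default 1.2 mm).
#' @param stripDf vertical-curve/scan smoothing df (default 8).
#' @param threshold midline evidence threshold (default 5).
#' @param boundaryDf boundary-fit df (default 25).
#' @param kappaFactor shape-penalty multiple of lambda (default 100).
#' @param up,right approximate orientation hints.
#' @return list with \code{curves} (\linkS4class{LipCurves}),
#'   \code{corners}, per-strip \code{results} and a \code{report}.
#' @export
lipBoundaries <- function(cloud, k = 50L, delta = 1.2, stripDf = 8,
                          threshold = 5, boundaryDf = 25, kappaFactor = 100,
                          up = c(0, 1, 0), right = c(1, 0, 0)) {
  vs <- verticalStrips(cloud, k = k, delta = delta, up = up, right = right)
  results <- lapply(seq_along(vs$strips), function(i) {
    r <- detectLipPoints(vs$strips[[i]], df = stripDf,
                         threshold = threshold)
    r$strip <- vs$strips[[i]]
    r$index <- i
    r
  })
  midPts <- do.call(rbind, lapply(results, function(r)
    if (!is.null(r$midline)) matrix(r$midline$point, 1) else NULL))
  if (is.null(midPts) || nrow(midPts) < 10L)
    stop("midline detected on fewer than 10 strips")
  cornerInfo <- findCorners(midPts)
  up1 <- resolveMultipleCandidates(results, "upper")
  lo1 <- resolveMultipleCandidates(results, "lower")
  curves <- fitLipBoundaries(results, up1, lo1, cornerInfo, vs,
                             df = boundaryDf, kappaFactor = kappaFactor)
  nDet <- sum(vapply(results, function(r) !is.null(r$midline), TRUE))
  list(curves = curves, corners = cornerInfo, results = results,
       frame = vs,
       report = list(k = k, nMidline = nDet,
                     nUpper = sum(vapply(up1, nrow, 0L) == 1L),
                     nLower = sum(vapply(lo1, nrow, 0L) == 1L),
                     sL = cornerInfo$sL, sR = cornerInfo$sR))
}
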