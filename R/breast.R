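# End-to-end breast boundary estimation: radial transects swept about the
# most prominent point (prom), per-transect principal curves and curvature
# maxima as boundary candidates, landmark-based exclusion rules, gap
# interpolation from flanking side curves, and a closed 3D boundary fit.

#' Closed 3D boundary curve over radial transects
#'
#' @slot models per-coordinate P-spline smooths over transect angle.
#' @slot angles transect angles (radians).
#' @slot points per-transect boundary points, k x 3 (mm).
#' @slot interpolated logical flag per transect.
#' @slot grid dense evaluation of the closed curve, n x 3.
#' @slot gridAngles angles of the dense evaluation.
#' @slot sGrid cumulative arc length of the dense evaluation (mm).
#' @export
setClass("BoundaryCurve3D",
  representation(models = "list", angles = "numeric", points = "matrix",
                 interpolated = "logical", grid = "matrix",
                 gridAngles = "numeric", sGrid = "numeric"))

setMethod("show", "BoundaryCurve3D", function(object) {
  cat(sprintf(
    "BoundaryCurve3D: %d transects (%d interpolated), arc length %.1f mm\n",
    length(object@angles), sum(object@interpolated), max(object@sGrid)))
})

# midline plane through ssn and xipho, approximately orthogonal to the
# surface; returns its unit normal and the sign of prom's side
.midlinePlane <- function(cloud, landmarks, radius = 12) {
  ssn <- landmark(landmarks, "ssn")
  xipho <- landmark(landmarks, "xipho")
  m <- .unit(ssn - xipho)
  n3s <- frameN3(localFrame(cloud, ssn, radius))
  n3x <- frameN3(localFrame(cloud, xipho, radius))
  nAvg <- .unit(n3s + n3x)
  u <- .unit(.cross(m, nAvg))
  prom <- landmark(landmarks, "prom")
  list(point = xipho, normal = u, m = m, nAvg = nAvg,
       promSign = sign(sum((prom - xipho) * u)))
}

# drop strip members on the far side of the midline plane
.truncateAtMidline <- function(strip, plane) {
  sgn <- drop(sweep(strip@points, 2, plane$point) %*% plane$normal) *
    plane$promSign
  keep <- sgn > 0
  new("TransectStrip", points = strip@points[keep, , drop = FALSE],
      frame = strip@frame,
      coords = strip@coords[keep, , drop = FALSE],
      delta = strip@delta, half = strip@half)
}

#' Radial transect strips about prom
#'
#' Builds a local frame at \emph{prom} (n1 initially toward \emph{lat}),
#' sweeps it clockwise in equal angular steps, and extracts half-strips of
#' slab tolerance \code{delta}.  Each strip is truncated at the midline
#' plane containing \emph{ssn} and \emph{xipho} (so a transect never crosses
#' to the other breast); optional per-transect length caps implement the
#' 1.5x stopping rule when candidate arc lengths are fed back by the
#' pipeline driver.
#'
#' @param cloud a \linkS4class{SurfacePointCloud}.
#' @param landmarks \linkS4class{LandmarkSet} with prom, lat, ssn, xipho.
#' @param nTransects number of radial directions (default 51).
#' @param delta slab half-tolerance, mm (default 1).
#' @param radius neighbourhood radius for the prom frame (default 12 mm).
#' @param maxLengths optional numeric vector of abscissa caps per transect.
#' @return list of \linkS4class{TransectStrip} (possibly empty strips, with
#'   a warning recorded rather than an error).
#' @export
radialTransects <- function(cloud, landmarks, nTransects = 51L, delta = 1,
                            radius = 12, maxLengths = NULL) {
  if (nTransects < 8L) stop("need at least 8 transects")
  prom <- landmark(landmarks, "prom")
  lat <- landmark(landmarks, "lat")
  frame0 <- localFrame(cloud, prom, radius, refDirection = lat - prom)
  plane <- .midlinePlane(cloud, landmarks, radius)
  lapply(seq_len(nTransects), function(j) {
    fr <- rotateFrame(frame0, 2 * pi * (j - 1L) / nTransects)
    cap <- if (is.null(maxLengths)) Inf else maxLengths[j]
    st <- suppressWarnings(
      planarStrip(cloud, fr, delta, half = TRUE, maxAbscissa = cap))
    .truncateAtMidline(st, plane)
  })
}

#' Boundary candidates on transect strips
#'
#' Fits the in-plane principal curve of each strip (df 6 by default),
#' computes its signed planar curvature and collects the positive local
#' maxima as boundary candidates, with 3D positions recovered from the
#' strip plane.
#'
#' @param strips list of \linkS4class{TransectStrip}.
#' @param df per-transect smoothing degrees of freedom (default 6).
#' @return list (one entry per strip) of data.frames with columns
#'   \code{s}, \code{kappa}, \code{x}, \code{y}, \code{z}; 0-row when a
#'   strip yields no positive maxima or is too small to fit.
#' @export
candidateBoundaryPoints <- function(strips, df = 6) {
  lapply(strips, function(st) {
    empty <- data.frame(s = numeric(), kappa = numeric(), x = numeric(),
                        y = numeric(), z = numeric())
    if (nrow(st@points) < df + 2) return(empty)
    crv <- tryCatch(stripCurve(st, df = df), error = function(e) NULL)
    if (is.null(crv)) return(empty)
    mx <- localCurvatureMaxima(planarCurvature(crv), requirePositive = TRUE)
    if (!nrow(mx)) return(empty)
    fp <- evalCurve(crv, mx$s)
    p3 <- .stripTo3D(st, fp[, 1], fp[, 2])
    data.frame(s = mx$s, kappa = mx$kappa,
               x = p3[, 1], y = p3[, 2], z = p3[, 3])
  })
}

#' Landmark-based candidate exclusion rules
#'
#' A candidate point c is retained iff all three hold:
#' (a) ||c - prom|| > proportion * min(||med - prom||, ||lat - prom||);
#' (b) min(med'n, lat'n) - tol <= c'n <= max(med'n, lat'n) + tol, where n is
#'     the unit average of the surface normals at ssn and xipho (protrusion);
#' (c) inf'm - tol < c'm < ssn'm, where m is the unit vector from xipho to
#'     ssn (elevation).
#' Projections use coordinates relative to the cloud centroid, applied
#' identically to candidates and landmark reference values, making the
#' inequalities origin-invariant.  The constants (default 0.7 and 10 mm)
#' are exposed because adjusting them is the intended manual-intervention
#' mechanism when a boundary estimate needs correction.
#'
#' @param candidates numeric matrix (n x 3) of candidate points.
#' @param landmarks \linkS4class{LandmarkSet} with prom, med, lat, inf,
#'   ssn, xipho.
#' @param cloud the source \linkS4class{SurfacePointCloud} (for normals and
#'   the reference origin).
#' @param proportion rule (a) proportion (default 0.7).
#' @param tolerance rules (b)/(c) tolerance in mm (default 10 = 1 cm).
#' @param radius neighbourhood radius for the ssn/xipho normals.
#' @return logical vector, TRUE = retained; attribute \code{"rule"} gives
#'   the first violated rule ("a", "b", "c" or "" when retained).
#' @export
filterCandidates <- function(candidates, landmarks, cloud,
                             proportion = 0.7, tolerance = 10, radius = 12) {
  candidates <- matrix(as.numeric(candidates), ncol = 3L)
  for (nm in c("prom", "med", "lat", "inf", "ssn", "xipho"))
    if (!nm %in% landmarkNames(landmarks))
      stop("missing landmark '", nm, "'")
  prom <- landmark(landmarks, "prom")
  med <- landmark(landmarks, "med")
  lat <- landmark(landmarks, "lat")
  infL <- landmark(landmarks, "inf")
  ssn <- landmark(landmarks, "ssn")
  xipho <- landmark(landmarks, "xipho")
  plane <- .midlinePlane(cloud, landmarks, radius)
  nvec <- plane$nAvg
  mvec <- plane$m
  origin <- colMeans(coords(cloud))
  pr <- function(p, v) sum((p - origin) * v)
  prMat <- function(P, v) drop(sweep(P, 2, origin) %*% v)
  dPro <- sqrt(rowSums(sweep(candidates, 2, prom)^2))
  aOk <- dPro > proportion * min(sqrt(sum((med - prom)^2)),
                                 sqrt(sum((lat - prom)^2)))
  cn <- prMat(candidates, nvec)
  bLo <- min(pr(med, nvec), pr(lat, nvec)) - tolerance
  bHi <- max(pr(med, nvec), pr(lat, nvec)) + tolerance
  bOk <- cn >= bLo & cn <= bHi
  cm <- prMat(candidates, mvec)
  cOk <- cm > pr(infL, mvec) - tolerance & cm < pr(ssn, mvec)
  keep <- aOk & bOk & cOk
  rule <- ifelse(!aOk, "a", ifelse(!bOk, "b", ifelse(!cOk, "c", "")))
  attr(keep, "rule") <- rule
  keep
}

# fit a df-capped P-spline of each coordinate against angle over the data
# window; prediction beyond the window extends the end tangent (basis
# columns with no data support would otherwise make the system singular)
.sideCurvePredict <- function(theta, P, predictAt, df = 12) {
  dfUse <- min(df, length(theta) - 2L)
  if (dfUse < 2) {  # too few points: linear extrapolation
    fit <- apply(P, 2, function(y) {
      cf <- coef(lm(y ~ theta))
      cf[1] + cf[2] * predictAt
    })
    return(matrix(fit, nrow = length(predictAt)))
  }
  nb <- max(dfUse + 2L, min(12L, length(theta) - 1L))
  rng <- range(theta)
  out <- vapply(seq_len(ncol(P)), function(j) {
    m <- fitPspline(theta, P[, j], nbasis = nb, df = dfUse, srange = rng)
    v <- psplineEval(m, pmin(pmax(predictAt, rng[1]), rng[2]))
    lo <- predictAt < rng[1]; hi <- predictAt > rng[2]
    if (any(lo))
      v[lo] <- psplineEval(m, rng[1]) +
        (predictAt[lo] - rng[1]) * psplineEval(m, rng[1], deriv = 1L)
    if (any(hi))
      v[hi] <- psplineEval(m, rng[2]) +
        (predictAt[hi] - rng[2]) * psplineEval(m, rng[2], deriv = 1L)
    v
  }, numeric(length(predictAt)))
  matrix(out, nrow = length(predictAt))
}

#' Interpolate boundary points across candidate gaps
#'
#' For a gap of l consecutive transects without a usable boundary point,
#' side curves are fitted (against transect angle) to the retained points
#' flanking the gap and extended across it; gap transect i receives the
#' weighted average ((l + 1 - i) * bL_i + i * bR_i) / (l + 1).
#'
#' @param points k x 3 matrix of per-transect boundary points with NA rows
#'   at gap transects.
#' @param angles transect angles (radians, length k, cyclic).
#' @param df side-curve smoothing df (default 12).
#' @param sideWindow number of flanking transects used per side (default 10).
#' @return list with completed \code{points} and logical
#'   \code{interpolated}.
#' @export
interpolateGaps <- function(points, angles, df = 12, sideWindow = 10L) {
  k <- nrow(points)
  miss <- !stats::complete.cases(points)
  if (!any(miss))
    return(list(points = points, interpolated = rep(FALSE, k)))
  if (sum(miss) > k / 2)
    stop("gaps span more than half the transects; boundary unidentifiable")
  have <- which(!miss)
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- points
  for (ri in which(runs$values)) {
    gap <- starts[ri]:ends[ri]
    l <- length(gap)
    # cyclic flanking indices
    before <- ((gap[1] - 2L + k) %% k) + 1L
    after <- (gap[l] %% k) + 1L
    # if the run touches the vector ends it may wrap; walk outwards
    left <- integer(); idx <- gap[1]
    while (length(left) < sideWindow) {
      idx <- ((idx - 2L + k) %% k) + 1L
      if (idx %in% gap) break
      if (!miss[idx]) left <- c(idx, left)
      if (length(left) + length(gap) >= k) break
    }
    right <- integer(); idx <- gap[l]
    while (length(right) < sideWindow) {
      idx <- (idx %% k) + 1L
      if (idx %in% gap) break
      if (!miss[idx]) right <- c(right, idx)
      if (length(right) + length(gap) >= k) break
    }
    if (!length(left) || !length(right))
      stop("gap has no flanking boundary points")
    # unwrap angles so each side and the gap are monotone
    unwrap <- function(th, refIdx) {
      th + 2 * pi * round((angles[refIdx] - th) / (2 * pi) - 0.5) * 0
    }
    thGap <- angles[gap]
    thL <- angles[left]; thR <- angles[right]
    # shift by 2*pi where the cyclic order wrapped
    fix <- function(th, anchor) th + 2 * pi * ((th - anchor) < -pi) -
      2 * pi * ((th - anchor) > pi)
    thL <- fix(thL, thGap[1]); thR <- fix(thR, thGap[l])
    bL <- .sideCurvePredict(thL, points[left, , drop = FALSE], thGap, df)
    bR <- .sideCurvePredict(thR, points[right, , drop = FALSE], thGap, df)
    wi <- seq_len(l)
    w <- (l + 1 - wi) / (l + 1)
    out[gap, ] <- w * bL + (1 - w) * bR
  }
  list(points = out, interpolated = miss)
}

#' Fit a closed 3D boundary curve through per-transect points
#'
#' Smooths each coordinate against transect angle with a P-spline at
#' \code{df} degrees of freedom (default 12).  Closure is achieved by a
#' periodic continuation device: a fraction of the angle-ordered points is
#' duplicated beyond each end (shifted by 2 pi) before smoothing, and the
#' fit is trimmed back to one period.
#'
#' @param points k x 3 matrix of boundary points (no NAs).
#' @param angles transect angles in [0, 2 pi).
#' @param df smoothing degrees of freedom (default 12).
#' @param interpolated optional logical flags carried through.
#' @param wrapFrac fraction of points duplicated at each end (default 0.15).
#' @param nGrid dense evaluation size (default 720).
#' @return a \linkS4class{BoundaryCurve3D}; start and end of the dense
#'   evaluation coincide to well under 1 mm.
#' @export
fitBoundary <- function(points, angles, df = 12, interpolated = NULL,
                        wrapFrac = 0.15, nGrid = 720L) {
  k <- nrow(points)
  if (k < df + 2) stop("need at least df + 2 = ", df + 2, " boundary points")
  gapsz <- max(diff(sort(c(angles, angles[1] + 2 * pi))))
  if (gapsz > pi / 2)
    stop("angular coverage gap exceeds 90 degrees; cannot close the curve")
  o <- order(angles)
  th <- angles[o]; P <- points[o, , drop = FALSE]
  nw <- max(2L, ceiling(wrapFrac * k))
  thExt <- c(th[(k - nw + 1L):k] - 2 * pi, th, th[1:nw] + 2 * pi)
  PExt <- rbind(P[(k - nw + 1L):k, ], P, P[1:nw, ])
  dfFit <- df * (1 + 2 * nw / k)   # keep ~df over the central period
  nb <- max(ceiling(dfFit) + 4L, 20L)
  models <- lapply(1:3, function(j)
    fitPspline(thExt, PExt[, j], nbasis = nb, df = dfFit,
               srange = range(thExt)))
  ga <- seq(0, 2 * pi, length.out = nGrid)
  G <- vapply(models, psplineEval, numeric(nGrid), s = ga)
  sG <- c(0, cumsum(sqrt(rowSums(diff(G)^2))))
  if (is.null(interpolated)) interpolated <- rep(FALSE, k)
  new("BoundaryCurve3D", models = models, angles = th, points = P,
      interpolated = interpolated[o], grid = G, gridAngles = ga, sGrid = sG)
}

#' Evaluate a closed boundary curve at given angles
#'
#' @param boundary a \linkS4class{BoundaryCurve3D}.
#' @param angles angles in radians (wrapped into the fitted period).
#' @return length(angles) x 3 matrix.
#' @export
evalBoundary <- function(boundary, angles) {
  angles <- angles %% (2 * pi)
  out <- vapply(boundary@models, psplineEval, numeric(length(angles)),
                s = angles)
  matrix(out, nrow = length(angles))
}

#' Run the breast boundary pipeline
#'
#' Sweeps radial transects about prom with the midline-plane and 1.5x
#' length stopping rules, collects positive curvature maxima as boundary
#' candidates, applies the landmark exclusion rules, keeps transects with
#' exactly one retained candidate, interpolates the remaining transects
#' from flanking side curves, and fits the closed boundary curve.
#'
#' @param cloud a \linkS4class{SurfacePointCloud}.
#' @param landmarks canonical per-breast \linkS4class{LandmarkSet}
#'   (see \code{\link{sideLandmarks}}).
#' @param nTransects number of radial transects (default 51).
#' @param delta slab half-tolerance, mm (default 1).
#' @param df per-transect smoothing df (default 6).
#' @param boundaryDf boundary-curve smoothing df (default 12).
#' @param radius prom-frame neighbourhood radius, mm (default 12).
#' @param proportion,tolerance exclusion-rule constants (defaults 0.7 and
#'   10 mm).
#' @param lengthFactor transect length cap as a multiple of the maximum
#'   candidate arc length in the two previous transects (default 1.5).
#' @return list with the \code{boundary} (\linkS4class{BoundaryCurve3D}),
#'   per-transect \code{strips}, \code{candidates}, \code{retained} flags
#'   and a \code{report} of counts.
#' @export
breastBoundary <- function(cloud, landmarks, nTransects = 51L, delta = 1,
                           df = 6, boundaryDf = 12, radius = 12,
                           proportion = 0.7, tolerance = 10,
                           lengthFactor = 1.5) {
  prom <- landmark(landmarks, "prom")
  lat <- landmark(landmarks, "lat")
  frame0 <- localFrame(cloud, prom, radius, refDirection = lat - prom)
  plane <- .midlinePlane(cloud, landmarks, radius)
  k <- as.integer(nTransects)
  strips <- vector("list", k)
  cands <- vector("list", k)
  retained <- vector("list", k)
  # arc lengths of retained candidates on the two previous transects that
  # produced any; these feed the 1.5x length cap
  lastMax <- c(NA_real_, NA_real_)
  oneTransect <- function(j, cap) {
    fr <- rotateFrame(frame0, 2 * pi * (j - 1L) / k)
    st <- suppressWarnings(
      planarStrip(cloud, fr, delta, half = TRUE, maxAbscissa = cap))
    st <- .truncateAtMidline(st, plane)
    cd <- candidateBoundaryPoints(list(st), df = df)[[1L]]
    keep <- if (nrow(cd))
      as.logical(filterCandidates(as.matrix(cd[, c("x", "y", "z")]),
                                  landmarks, cloud, proportion, tolerance,
                                  radius))
    else logical(0)
    list(strip = st, cand = cd, keep = keep)
  }
  for (j in seq_len(k)) {
    cap <- if (all(is.finite(lastMax))) lengthFactor * max(lastMax) else Inf
    r <- oneTransect(j, cap)
    strips[[j]] <- r$strip; cands[[j]] <- r$cand; retained[[j]] <- r$keep
    if (any(r$keep)) lastMax <- c(lastMax[2], max(r$cand$s[r$keep]))
  }
  # the first transects ran uncapped; revisit them with the cap carried
  # cyclically from the end of the sweep
  if (all(is.finite(lastMax))) {
    for (j in 1:2) {
      r <- oneTransect(j, lengthFactor * max(lastMax))
      strips[[j]] <- r$strip; cands[[j]] <- r$cand; retained[[j]] <- r$keep
      if (any(r$keep)) lastMax <- c(lastMax[2], max(r$cand$s[r$keep]))
    }
  }
  ptMat <- matrix(NA_real_, k, 3L)
  nRetained <- 0L; nExcluded <- 0L
  for (j in seq_len(k)) {
    cd <- cands[[j]]
    keep <- retained[[j]]
    nExcluded <- nExcluded + sum(!keep)
    if (sum(keep) == 1L) {
      ptMat[j, ] <- as.numeric(cd[keep, c("x", "y", "z")])
      nRetained <- nRetained + 1L
    }
  }
  angles <- 2 * pi * (seq_len(k) - 1L) / k
  ig <- interpolateGaps(ptMat, angles, df = boundaryDf)
  boundary <- fitBoundary(ig$points, angles, df = boundaryDf,
                          interpolated = ig$interpolated)
  list(boundary = boundary, strips = strips, candidates = cands,
       retained = retained,
       report = list(nTransects = k, nRetained = nRetained,
                     nExcluded = nExcluded,
                     nInterpolated = sum(ig$interpolated)))
}

#' Minimum distances from points to a polyline
#'
#' Utility for validating estimated curves against dense ground-truth
#' polylines: exact point-to-segment distances.
#'
#' @param P n x d points.
#' @param L m x d polyline vertices (consecutive vertices joined).
#' @return numeric(n) distances.
#' @export
polylineDistance <- function(P, L) {
  P <- as.matrix(P); L <- as.matrix(L)
  n <- nrow(P)
  A <- L[-nrow(L), , drop = FALSE]
  Bv <- L[-1, , drop = FALSE] - A
  bb <- rowSums(Bv^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- sweep(A, 2, P[i, ], "-")
    t <- pmin(pmax(-rowSums(w * Bv) / pmax(bb, 1e-300), 0), 1)
    d2 <- rowSums((w + Bv * t)^2)
    out[i] <- sqrt(min(d2))
  }
  out
}
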