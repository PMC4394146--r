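# Principal curves in 2D and 3D.  A principal curve f(s) is self-consistent:
# its location at arc length s is the mean of the data points that project
# there.  The sample version alternates (i) projecting the points onto the
# current curve to get arc lengths and (ii) smoothing each coordinate
# against those arc lengths with a penalized B-spline at fixed degrees of
# freedom, starting from the first linear principal component.

.pcNbasis <- function(df, n) {
  nb <- min(max(ceiling(df) + 10L, 15L), 50L)
  max(min(nb, n - 1L), ceiling(df) + 2L)
}

# Project points onto the polyline (sGrid, G); returns arc lengths and
# squared distances.  Chunked to bound memory on large clouds.
.projectPolyline <- function(P, G, sGrid) {
  n <- nrow(P); ng <- nrow(G)
  sOut <- numeric(n); d2Out <- numeric(n)
  gss <- rowSums(G^2)
  chunk <- max(1L, floor(2e6 / ng))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    Pc <- P[idx, , drop = FALSE]
    D2 <- outer(rowSums(Pc^2), gss, "+") - 2 * tcrossprod(Pc, G)
    near <- max.col(-D2, ties.method = "first")
    for (jj in seq_along(idx)) {
      i <- near[jj]
      p <- Pc[jj, ]
      best <- c(sGrid[i], D2[jj, i])
      for (seg in c(i - 1L, i)) {
        if (seg < 1L || seg >= ng) next
        A <- G[seg, ]; Bv <- G[seg + 1L, ] - A
        bb <- sum(Bv^2)
        if (bb < .Machine$double.eps) next
        t <- min(max(sum((p - A) * Bv) / bb, 0), 1)
        q <- A + t * Bv
        dd <- sum((p - q)^2)
        if (dd < best[2])
          best <- c(sGrid[seg] + t * (sGrid[seg + 1L] - sGrid[seg]), dd)
      }
      sOut[idx[jj]] <- best[1]
      d2Out[idx[jj]] <- best[2]
    }
  }
  list(s = sOut, dist2 = d2Out)
}

#' Fit a principal curve
#'
#' Alternates projection and per-coordinate P-spline smoothing until the
#' relative change in total squared projection distance falls below
#' \code{tol} or \code{maxIter} is reached.  Initialisation is from first
#' principal component scores; the parameterisation is cumulative chord
#' length along a dense evaluation grid, so \code{s} is arc length in mm.
#'
#' @param X n x d matrix of points (d = 2 or 3), in mm.
#' @param df smoothing degrees of freedom per coordinate (default 6, the
#'   value used for breast transects; lip transects use 8).
#' @param maxIter iteration cap (default 20).
#' @param tol relative convergence tolerance on the total squared projection
#'   distance (default 1e-4).
#' @param nGrid dense evaluation grid size (default 512).
#' @param startNear optional point; the curve is oriented so that s = 0 is
#'   the end nearer to it (e.g. the transect origin at \emph{prom}).
#' @return a \linkS4class{PrincipalCurve}; \code{converged} is FALSE when
#'   the best iterate was returned at the cap.
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' X <- cbind(50 * cos(th), 50 * sin(th)) + rnorm(400, sd = 0.5)
#' fitPrincipalCurve(X, df = 6)
#' @export
fitPrincipalCurve <- function(X, df = 6, maxIter = 20L, tol = 1e-4,
                              nGrid = 512L, startNear = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  n <- nrow(X)
  stopifnot(d %in% c(2L, 3L))
  if (df < 2) stop("df must be at least 2")
  if (n < df + 2) stop("need at least df + 2 = ", df + 2, " points, have ", n)
  nb <- .pcNbasis(df, n)
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr), nu = 0L, nv = 1L)
  s <- drop(sweep(X, 2, ctr) %*% sv$v[, 1L])
  if (!is.null(startNear)) {
    e0 <- X[which.min(s), ]; e1 <- X[which.max(s), ]
    if (sum((e0 - startNear)^2) > sum((e1 - startNear)^2)) s <- -s
  }
  prevDist <- Inf
  converged <- FALSE
  models <- NULL; sGrid <- NULL; G <- NULL; distSq <- NA_real_
  for (it in seq_len(maxIter)) {
    s <- s - min(s)
    rng <- range(s)
    if (diff(rng) < .Machine$double.eps) stop("degenerate projection index")
    models <- lapply(seq_len(d), function(j)
      fitPspline(s, X[, j], nbasis = nb, df = df, srange = rng))
    tg <- seq(rng[1], rng[2], length.out = nGrid)
    G <- vapply(models, psplineEval, numeric(nGrid), s = tg)
    seglen <- sqrt(rowSums(diff(G)^2))
    sGrid <- c(0, cumsum(seglen))
    pr <- .projectPolyline(X, G, sGrid)
    distSq <- sum(pr$dist2)
    if (is.finite(prevDist) &&
        abs(prevDist - distSq) <= tol * max(prevDist, .Machine$double.eps)) {
      s <- pr$s
      converged <- TRUE
      break
    }
    prevDist <- distSq
    s <- pr$s
  }
  # final refit against the converged arc lengths
  s <- s - min(s)
  rng <- range(s)
  models <- lapply(seq_len(d), function(j)
    fitPspline(s, X[, j], nbasis = nb, df = df, srange = rng))
  tg <- seq(rng[1], rng[2], length.out = nGrid)
  G <- vapply(models, psplineEval, numeric(nGrid), s = tg)
  new("PrincipalCurve", dim = as.integer(d), models = models, s = s,
      smax = rng[2], sGrid = tg, grid = G, df = rep(df, d),
      converged = converged, distSq = distSq)
}

#' Evaluate a principal curve at given arc lengths
#'
#' @param curve a \linkS4class{PrincipalCurve}.
#' @param s arc lengths in [0, smax] (clamped to the basis span).
#' @param deriv derivative order (0, 1 or 2).
#' @return length(s) x dim matrix.
#' @export
evalCurve <- function(curve, s, deriv = 0L) {
  out <- vapply(curve@models, psplineEval, numeric(length(s)),
                s = s, deriv = deriv)
  if (is.null(dim(out))) out <- matrix(out, nrow = length(s))
  out
}

#' Project points onto a principal curve
#'
#' Finds for each point the arc length minimising the distance to the curve,
#' by nearest-vertex search on the dense evaluation grid followed by local
#' refinement (exact projection onto the adjacent polyline segments and,
#' optionally, 1D optimisation of the spline distance).  Ties between arcs
#' resolve to the smallest arc length.
#'
#' @param curve a \linkS4class{PrincipalCurve}.
#' @param points a point (numeric vector) or matrix of points.
#' @param refine logical; run a local continuous optimisation (default TRUE).
#' @return data.frame with columns \code{s}, \code{distance}, and foot-point
#'   coordinates \code{f1..fd}.
#' @export
projectToCurve <- function(curve, points, refine = TRUE) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  pr <- .projectPolyline(points, curve@grid, curve@sGrid)
  s <- pr$s
  d2 <- pr$dist2
  if (refine) {
    h <- diff(curve@sGrid[1:2])
    for (i in seq_len(nrow(points))) {
      p <- points[i, ]
      f <- function(ss) sum((evalCurve(curve, ss)[1, ] - p)^2)
      op <- optimize(f, c(max(0, s[i] - h), min(curve@smax, s[i] + h)))
      if (op$objective < d2[i]) {
        s[i] <- op$minimum
        d2[i] <- op$objective
      }
    }
  }
  fp <- evalCurve(curve, s)
  out <- data.frame(s = s, distance = sqrt(d2))
  colnames(fp) <- paste0("f", seq_len(ncol(fp)))
  cbind(out, fp)
}

#' Extrapolate a principal curve beyond its ends
#'
#' Linear extrapolation of each coordinate using the end-point value and
#' end-point first derivative (tangent line).
#'
#' @param curve a \linkS4class{PrincipalCurve}.
#' @param sBeyond arc lengths at or outside [0, smax].
#' @return length(sBeyond) x dim matrix of predicted points.
#' @export
extendCurve <- function(curve, sBeyond) {
  smax <- curve@smax
  inside <- sBeyond > 0 & sBeyond < smax &
    abs(sBeyond) > 1e-12 & abs(sBeyond - smax) > 1e-12
  if (any(inside))
    stop("extendCurve requires arc lengths outside [0, smax]")
  out <- matrix(NA_real_, length(sBeyond), curve@dim)
  for (i in seq_along(sBeyond)) {
    sb <- sBeyond[i]
    endS <- if (sb >= smax) smax else 0
    f0 <- evalCurve(curve, endS)[1, ]
    f1 <- evalCurve(curve, endS, deriv = 1L)[1, ]
    out[i, ] <- f0 + (sb - endS) * f1
  }
  out
}

#' Serialise a principal curve to CSV
#'
#' Writes the dense evaluation grid as columns s, x, y (and z for 3D).
#'
#' @param curve a \linkS4class{PrincipalCurve}.
#' @param path output path.
#' @export
writeCurveCSV <- function(curve, path) {
  df <- data.frame(s = curve@sGrid)
  nm <- c("x", "y", "z")[seq_len(curve@dim)]
  for (j in seq_len(curve@dim)) df[[nm[j]]] <- curve@grid[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
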