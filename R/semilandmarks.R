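# Semi-landmark regularisation: bounded anatomical surfaces are resampled
# into corresponded point grids.  Holding the number of transects, the
# starting orientation, the per-transect point counts and the proportionate
# arc-length positions constant yields point-to-point correspondence across
# specimens, so the grids feed directly into Procrustes/PCA shape analysis.

#' Exponential-quantile spacing sequence
#'
#' A sequence tau_1 < ... < tau_r = 1 in (0, 1] built from equally spaced
#' quantiles of the exponential distribution, normalised by the quantile at
#' \code{pmax}.  Applied from the apex outward as s_i = smax * (1 - tau_(r-i)),
#' the gaps are largest next to the apex and decrease strictly toward the
#' boundary — points are selected more sparsely where the radial transects
#' converge, for a more regular spacing across the surface.
#'
#' @param r number of points per transect (default 20).
#' @param pmax probability cap for the (unbounded) exponential quantile
#'   function (default 0.99).
#' @return numeric(r), strictly increasing, last element exactly 1.
#' @export
exponentialSpacings <- function(r = 20L, pmax = 0.99) {
  if (r < 2L) stop("r must be at least 2")
  qexp(seq_len(r) * pmax / r) / qexp(pmax)
}

# arc positions from the apex (s = 0) to the boundary (s = smax)
.apexSpacings <- function(r, smax, pmax = 0.99) {
  tau <- c(0, exponentialSpacings(r, pmax))
  smax * (1 - tau[r:1])
}

#' Breast semi-landmark grid
#'
#' Resamples the surface inside an estimated breast boundary into the apex
#' (prom) plus r points on each of the k radial transects, at exponential-
#' quantile proportional arc lengths from prom to the boundary crossing
#' (the last point of every transect lies on the boundary).
#'
#' @param result output of \code{\link{breastBoundary}}.
#' @param landmarks the landmark set used for the pipeline (for prom).
#' @param r points per transect (default 20).
#' @param df per-transect smoothing df (default 6, as in the pipeline).
#' @param pmax exponential quantile cap (default 0.99).
#' @return a \linkS4class{SemiLandmarkGrid} with 1 + k * r points (1021 for
#'   the default k = 51, r = 20).
#' @export
breastSemilandmarks <- function(result, landmarks, r = 20L, df = 6,
                                pmax = 0.99) {
  strips <- result$strips
  bnd <- result$boundary
  k <- length(strips)
  prom <- landmark(landmarks, "prom")
  pts <- matrix(NA_real_, 1L + k * r, 3L)
  pts[1L, ] <- prom
  lab <- data.frame(transect = c(0L, rep(seq_len(k), each = r)),
                    index = c(0L, rep(seq_len(r), k)))
  for (j in seq_len(k)) {
    st <- strips[[j]]
    if (nrow(st@points) < df + 2)
      stop("transect ", j, " has no usable boundary crossing")
    crv <- stripCurve(st, df = df)
    b3 <- evalBoundary(bnd, bnd@angles[j])[1, ]   # smoothed boundary crossing
    fr <- st@frame
    rel <- b3 - fr@origin
    b2 <- c(sum(rel * fr@axes[, 1L]), sum(rel * fr@axes[, 3L]))
    sB <- projectToCurve(crv, b2)$s
    sPos <- .apexSpacings(r, sB, pmax)
    fp <- evalCurve(crv, sPos)
    pts[1L + (j - 1L) * r + seq_len(r), ] <- .stripTo3D(st, fp[, 1], fp[, 2])
  }
  counts <- c(1L, rep(r, k))
  new("SemiLandmarkGrid", points = pts, labels = lab,
      descriptor = list(kind = "breast", k = k, r = r, pmax = pmax,
                        df = df, counts = counts))
}

# equally spaced interior arc positions between two projections
.betweenArcs <- function(sA, sB, nInterior) {
  seq(sA, sB, length.out = nInterior + 2L)
}

#' Lip semi-landmark grid
#'
#' For one lip (the surface between a boundary ridge curve and the
#' midline): \code{nBoundary} points equally spaced in arc length on each
#' of the two bounding curves are taken in corresponding pairs, and each
#' pair is joined by a cross-lip transect — a principal curve through the
#' strip of surface points between them — carrying a number of interior
#' semi-landmarks that ramps with lip width from \code{minInterior} at the
#' corners to \code{maxInterior} at the widest point (piecewise-linear
#' profile, rounded).  Each pair contributes its two boundary points plus
#' the interior points, transect-major; the total count is a deterministic
#' function of the descriptor.
#'
#' @param fit a \linkS4class{LipCurves}.
#' @param cloud the mouth-region cloud (for the cross-lip strips).
#' @param lip "upper" or "lower".
#' @param nBoundary points per boundary curve (default 50).
#' @param minInterior,maxInterior interior-count ramp endpoints (defaults
#'   3 and 24).
#' @param df cross-transect smoothing df (default 4).
#' @param delta cross-strip slab half-tolerance, mm (default 1.2).
#' @return a \linkS4class{SemiLandmarkGrid}.
#' @export
lipSemilandmarks <- function(fit, cloud, lip = c("upper", "lower"),
                             nBoundary = 50L, minInterior = 3L,
                             maxInterior = 24L, df = 4, delta = 1.2) {
  lip <- match.arg(lip)
  sSeq <- seq(fit@sL, fit@sR, length.out = nBoundary)
  outPts <- evalLipCurve(fit, lip, sSeq)
  inPts <- evalLipCurve(fit, "midline", sSeq)
  w <- 1 - abs(2 * (seq_len(nBoundary) - 1L) / (nBoundary - 1L) - 1)
  w <- w / max(w)   # the widest pair gets exactly maxInterior
  counts <- as.integer(round(minInterior + (maxInterior - minInterior) * w))
  P <- coords(cloud)
  n1 <- fit@frameAxes[, 1L]
  ptsList <- vector("list", nBoundary)
  for (i in seq_len(nBoundary)) {
    a <- outPts[i, ]; b <- inPts[i, ]
    ci <- counts[i]
    lin <- function() {
      t <- seq(0, 1, length.out = ci + 2L)
      outer(1 - t, a) + outer(t, b)
    }
    mid <- (a + b) / 2
    off <- drop(sweep(P, 2, mid) %*% n1)
    gap <- sqrt(sum((a - b)^2))
    sel <- abs(off) <= delta &
      rowSums(sweep(P, 2, mid)^2) <= (gap / 2 + 3 * delta)^2
    pts <- if (sum(sel) >= df + 4) {
      X <- P[sel, , drop = FALSE]
      tr <- tryCatch(fitPrincipalCurve(X, df = df, startNear = a),
                     error = function(e) NULL)
      if (is.null(tr)) lin() else {
        sA <- projectToCurve(tr, a, refine = FALSE)$s
        sB <- projectToCurve(tr, b, refine = FALSE)$s
        sc <- .betweenArcs(sA, sB, ci)
        Q <- evalCurve(tr, sc)
        Q[1L, ] <- a; Q[ci + 2L, ] <- b   # pin the endpoints to the curves
        Q
      }
    } else lin()
    ptsList[[i]] <- pts
  }
  pts <- do.call(rbind, ptsList)
  lab <- data.frame(
    transect = rep(seq_len(nBoundary), times = counts + 2L),
    index = unlist(lapply(counts + 2L, seq_len)))
  new("SemiLandmarkGrid", points = pts, labels = lab,
      descriptor = list(kind = "lip", lip = lip, nBoundary = nBoundary,
                        minInterior = minInterior,
                        maxInterior = maxInterior, df = df,
                        counts = counts + 2L))
}

#' Triangulate a semi-landmark grid
#'
#' Breast grids get an apex fan (k triangles) plus quads split into
#' triangles between successive rings: 2 k (r - 1) + k faces in total,
#' closing cyclically.  Lip grids (variable per-transect counts) are sewn
#' between consecutive transects by monotone merging on normalised
#' position.  Degenerate (zero-area) faces are dropped with a warning.
#'
#' @param grid a \linkS4class{SemiLandmarkGrid}.
#' @return integer matrix, nFaces x 3, of 1-based point indices.
#' @export
triangulateGrid <- function(grid) {
  desc <- grid@descriptor
  faces <- if (identical(desc$kind, "breast")) {
    k <- desc$k; r <- desc$r
    idx <- function(t, i) 1L + (t - 1L) * r + i   # apex is index 1
    f <- vector("list", k)
    for (t in seq_len(k)) {
      t2 <- if (t == k) 1L else t + 1L
      fan <- c(1L, idx(t, 1L), idx(t2, 1L))
      quads <- lapply(seq_len(r - 1L), function(i)
        rbind(c(idx(t, i), idx(t2, i), idx(t, i + 1L)),
              c(idx(t2, i), idx(t2, i + 1L), idx(t, i + 1L))))
      f[[t]] <- rbind(fan, do.call(rbind, quads))
    }
    do.call(rbind, f)
  } else {
    counts <- desc$counts
    offs <- cumsum(c(0L, counts))
    f <- list()
    for (t in seq_len(length(counts) - 1L)) {
      na <- counts[t]; nb <- counts[t + 1L]
      ua <- seq(0, 1, length.out = na)
      ub <- seq(0, 1, length.out = nb)
      i <- 1L; j <- 1L
      while (i < na || j < nb) {
        advanceA <- if (i == na) FALSE
          else if (j == nb) TRUE
          else ua[i + 1L] <= ub[j + 1L]
        tri <- if (advanceA) {
          c(offs[t] + i, offs[t + 1L] + j, offs[t] + i + 1L)
        } else {
          c(offs[t] + i, offs[t + 1L] + j, offs[t + 1L] + j + 1L)
        }
        f[[length(f) + 1L]] <- tri
        if (advanceA) i <- i + 1L else j <- j + 1L
      }
    }
    do.call(rbind, f)
  }
  P <- grid@points
  area2 <- vapply(seq_len(nrow(faces)), function(i) {
    v <- faces[i, ]
    sum(.cross(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ])^2)
  }, 0)
  bad <- area2 < 1e-20
  if (any(bad)) {
    warning(sum(bad), " degenerate faces dropped")
    faces <- faces[!bad, , drop = FALSE]
  }
  dimnames(faces) <- NULL
  faces
}

#' Write a semi-landmark grid as CSV
#'
#' Columns: specimen_id, transect_idx, point_idx, x, y, z.
#'
#' @param grid a \linkS4class{SemiLandmarkGrid}.
#' @param path output path.
#' @param specimen specimen identifier (default "specimen").
#' @export
writeGridCSV <- function(grid, path, specimen = "specimen") {
  utils::write.csv(data.frame(specimen_id = specimen,
                              transect_idx = grid@labels$transect,
                              point_idx = grid@labels$index,
                              x = grid@points[, 1], y = grid@points[, 2],
                              z = grid@points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a triangulated grid as OBJ
#'
#' @param grid a \linkS4class{SemiLandmarkGrid}.
#' @param path output path.
#' @param faces optional face matrix (computed if missing).
#' @export
writeGridOBJ <- function(grid, path, faces = NULL) {
  if (is.null(faces)) faces <- triangulateGrid(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", grid@points[, 1],
                     grid@points[, 2], grid@points[, 3]), con)
  writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  invisible(path)
}
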