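# Constructors, accessors and show methods for the core containers.

#' Create a surface point cloud
#'
#' @param points K x 3 numeric matrix of coordinates (mm).
#' @param normals optional K x 3 matrix of unit normals.
#' @param colours optional K x 3 matrix of colours in [0, 1].
#' @return a \linkS4class{SurfacePointCloud}.
#' @export
SurfacePointCloud <- function(points, normals = NULL, colours = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  new("SurfacePointCloud", points = points,
      normals = if (is.null(normals)) matrix(numeric(), 0, 3) else as.matrix(normals),
      colours = if (is.null(colours)) matrix(numeric(), 0, 3) else as.matrix(colours))
}

#' Create a named landmark set
#'
#' @param coords m x 3 matrix with rownames, or a data.frame with columns
#'   \code{name, x, y, z}.
#' @return a \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(coords) {
  if (is.data.frame(coords)) {
    nm <- as.character(coords$name)
    coords <- as.matrix(coords[, c("x", "y", "z")])
    rownames(coords) <- nm
  }
  storage.mode(coords) <- "double"
  new("LandmarkSet", coords = coords)
}

#' @describeIn SurfacePointCloud-class number of points
#' @param x object
#' @export
setMethod("length", "SurfacePointCloud", function(x) nrow(x@points))

#' Extract the coordinate matrix of a geometric object
#'
#' @param x a \linkS4class{SurfacePointCloud}, \linkS4class{LandmarkSet},
#'   \linkS4class{TransectStrip} or \linkS4class{SemiLandmarkGrid}.
#' @return numeric matrix of 3D coordinates (mm).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "SurfacePointCloud", function(x) x@points)
#' @rdname coords
#' @export
setMethod("coords", "LandmarkSet", function(x) x@coords)
#' @rdname coords
#' @export
setMethod("coords", "TransectStrip", function(x) x@points)
#' @rdname coords
#' @export
setMethod("coords", "SemiLandmarkGrid", function(x) x@points)

#' Landmark lookup by name
#'
#' @param x a \linkS4class{LandmarkSet}.
#' @param name landmark name.
#' @return numeric(3) coordinates.
#' @export
landmark <- function(x, name) {
  stopifnot(is(x, "LandmarkSet"))
  if (!name %in% rownames(x@coords))
    stop("landmark '", name, "' not present (have: ",
         paste(rownames(x@coords), collapse = ", "), ")")
  x@coords[name, ]
}

#' Landmark names
#' @param x a \linkS4class{LandmarkSet}.
#' @export
landmarkNames <- function(x) rownames(x@coords)

#' Frame axes accessors
#'
#' @param x a \linkS4class{LocalFrame}.
#' @return unit numeric(3) axis vector, or the origin.
#' @export
frameN1 <- function(x) x@axes[, 1L]
#' @rdname frameN1
#' @export
frameN2 <- function(x) x@axes[, 2L]
#' @rdname frameN1
#' @export
frameN3 <- function(x) x@axes[, 3L]
#' @rdname frameN1
#' @export
frameOrigin <- function(x) x@origin

#' In-plane coordinates of a transect strip
#'
#' @param x a \linkS4class{TransectStrip}.
#' @return n x 2 matrix (abscissa = projection on n1, ordinate = on n3).
#' @export
stripCoords <- function(x) x@coords

#' Arc-length range of a fitted curve
#' @param x a \linkS4class{PrincipalCurve}.
#' @export
curveSmax <- function(x) x@smax

#' Grid labels of a semi-landmark grid
#' @param x a \linkS4class{SemiLandmarkGrid}.
#' @export
gridLabels <- function(x) x@labels

#' Grid descriptor of a semi-landmark grid
#' @param x a \linkS4class{SemiLandmarkGrid}.
#' @export
gridDescriptor <- function(x) x@descriptor

setMethod("show", "SurfacePointCloud", function(object) {
  cat("SurfacePointCloud with", nrow(object@points), "points\n")
  rg <- apply(object@points, 2, range)
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
  if (nrow(object@normals) > 0L) cat("  per-point normals attached\n")
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet:", paste(rownames(object@coords), collapse = ", "), "\n")
})

setMethod("show", "LocalFrame", function(object) {
  cat("LocalFrame at (", paste(sprintf("%.2f", object@origin), collapse = ", "),
      ") mm\n", sep = "")
})

setMethod("show", "TransectStrip", function(object) {
  cat("TransectStrip:", nrow(object@points), "points, delta =", object@delta,
      "mm", if (object@half) "(half-strip)" else "", "\n")
})

setMethod("show", "PrincipalCurve", function(object) {
  cat(sprintf("PrincipalCurve (%dD): smax = %.2f mm, df = %.1f, %s\n",
              object@dim, object@smax, object@df[1],
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "PSplineModel", function(object) {
  cat(sprintf("PSplineModel: %d basis functions, lambda = %.3g, df = %.2f\n",
              length(object@beta), object@lambda, object@df))
})

setMethod("show", "ChangepointScan", function(object) {
  ok <- is.finite(object@T)
  cat(sprintf("ChangepointScan: %d grid points (%d usable), max |T| = %.2f\n",
              length(object@grid), sum(ok),
              if (any(ok)) max(abs(object@T[ok])) else NA_real_))
})

setMethod("show", "SemiLandmarkGrid", function(object) {
  cat("SemiLandmarkGrid with", nrow(object@points), "points;",
      "descriptor:", paste(names(object@descriptor), unlist(lapply(
        object@descriptor, function(v) paste(format(v), collapse = "/"))),
        sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ShapeSample", function(object) {
  d <- dim(object@configs)
  cat("ShapeSample:", d[3], "configurations of", d[1], "points\n")
})

setMethod("show", "ShapePCAModel", function(object) {
  cat("ShapePCAModel:", ncol(object@loadings), "components;",
      "leading sdevs:", paste(sprintf("%.3g", utils::head(object@sdev, 3)),
                              collapse = ", "), "\n")
})

# internal: unit vector
.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

# internal: cross product
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
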