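#' @import methods
#' @importFrom stats approx coef cor dist lm optimize prcomp qexp quantile
#'   rnorm runif sd t.test uniroot var
NULL

#' Unstructured 3D surface point cloud
#'
#' Represents an anatomical surface as a set of three-dimensional points
#' \eqn{\{p_i : i = 1, \dots, K\}} in millimetres, the raw output of
#' stereo-photogrammetry or laser scanning.  Points carry no connectivity;
#' all downstream algorithms operate on the point set alone.  Optional
#' per-point unit normals (used by the noise generator) and colours
#' (ignored by algorithms) may be attached.
#'
#' @slot points numeric matrix, K x 3, coordinates in mm.
#' @slot normals numeric matrix, K x 3 unit normals, or 0-row matrix.
#' @slot colours numeric matrix, K x 3 in [0, 1], or 0-row matrix.
#' @export
setClass("SurfacePointCloud",
  representation(points = "matrix", normals = "matrix", colours = "matrix"),
  prototype(points = matrix(numeric(), 0, 3),
            normals = matrix(numeric(), 0, 3),
            colours = matrix(numeric(), 0, 3)),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 3L) return("points must have 3 columns")
    if (nrow(p) < 3L) return("a surface needs at least 3 points")
    if (!all(is.finite(p))) return("points must be finite")
    if (nrow(object@normals) > 0L && !identical(dim(object@normals), dim(p)))
      return("normals must match points in dimension")
    TRUE
  })

#' Named anatomical landmarks
#'
#' A small set of named 3D points (mm).  Torso pipelines expect the names
#' \code{prom}, \code{med}, \code{lat}, \code{inf}, \code{ssn}, \code{xipho}
#' (per breast side where applicable); lip pipelines use seven conventional
#' lip landmarks (two cheilions plus five interior points).
#'
#' @slot coords numeric matrix, m x 3, with unique rownames as names.
#' @export
setClass("LandmarkSet",
  representation(coords = "matrix"),
  validity = function(object) {
    cc <- object@coords
    if (ncol(cc) != 3L) return("coords must have 3 columns")
    if (is.null(rownames(cc))) return("landmarks must be named (rownames)")
    if (anyDuplicated(rownames(cc))) return("landmark names must be unique")
    if (!all(is.finite(cc))) return("landmark coordinates must be finite")
    TRUE
  })

#' Local orthonormal coordinate frame
#'
#' Origin plus right-handed orthonormal axes (n1, n2, n3), typically from a
#' principal component analysis of a surface neighbourhood: n1 and n2 span
#' the local tangent plane and n3 (smallest-variance direction) is the
#' outward surface normal.
#'
#' @slot origin numeric(3), mm.
#' @slot axes 3 x 3 matrix whose columns are n1, n2, n3.
#' @export
setClass("LocalFrame",
  representation(origin = "numeric", axes = "matrix"),
  validity = function(object) {
    if (length(object@origin) != 3L) return("origin must be length 3")
    A <- object@axes
    if (!identical(dim(A), c(3L, 3L))) return("axes must be 3 x 3")
    if (max(abs(crossprod(A) - diag(3))) > 1e-9)
      return("axes must be orthonormal to 1e-9")
    TRUE
  })

#' Planar transect strip of surface points
#'
#' The set of cloud points lying within a thin planar slab
#' \eqn{|p^T n_2| \le \delta} around a cutting plane (optionally restricted
#' to the half-plane \eqn{p^T n_1 > 0}), with in-plane coordinates:
#' abscissa = projection on n1, ordinate = projection on n3 (all relative to
#' the frame origin).
#'
#' @slot points member points, n x 3 (mm).
#' @slot frame the generating \linkS4class{LocalFrame}.
#' @slot coords n x 2 in-plane coordinates (abscissa, ordinate), mm.
#' @slot delta slab half-tolerance, mm.
#' @slot half logical; TRUE for half-strips.
#' @export
setClass("TransectStrip",
  representation(points = "matrix", frame = "LocalFrame", coords = "matrix",
                 delta = "numeric", half = "logical"),
  validity = function(object) {
    if (ncol(object@points) != 3L) return("points must have 3 columns")
    if (nrow(object@coords) != nrow(object@points) || ncol(object@coords) != 2L)
      return("coords must be n x 2")
    if (object@delta < 0) return("delta must be non-negative")
    TRUE
  })

#' Penalized B-spline (P-spline) regression model
#'
#' Cubic B-spline regression \eqn{x = B\beta} with a second-difference
#' penalty \eqn{\lambda \beta^T D_2^T D_2 \beta}; optionally with equality
#' constraints through given points and iterated shape (monotonicity /
#' second-derivative pattern) penalties with parameter
#' \eqn{\kappa = 100\lambda} by default.
#'
#' @slot knots full knot vector.
#' @slot degree spline degree (3 = cubic).
#' @slot beta fitted coefficient vector (constrained, when applicable).
#' @slot betaUnc unconstrained coefficients.
#' @slot lambda smoothing parameter.
#' @slot kappa shape-penalty parameter (0 when unused).
#' @slot df effective degrees of freedom achieved (hat-matrix trace).
#' @slot srange covariate range covered by the basis.
#' @slot converged logical; FALSE if a shape-penalty mask loop hit its cap.
#' @export
setClass("PSplineModel",
  representation(knots = "numeric", degree = "integer", beta = "numeric",
                 betaUnc = "numeric", lambda = "numeric", kappa = "numeric",
                 df = "numeric", srange = "numeric", converged = "logical"))

#' Principal curve through a point set
#'
#' A smooth parametric curve \eqn{f(s)} indexed by arc length s, fitted so
#' that each coordinate is a penalized-spline smooth of the data against the
#' current projection arc lengths (the sample version of the self-consistency
#' property: the curve at s is the mean of points projecting to s).
#'
#' @slot dim 2 or 3.
#' @slot models list of per-coordinate \linkS4class{PSplineModel}s.
#' @slot s projection arc lengths of the training points (mm).
#' @slot smax total arc length (mm).
#' @slot sGrid dense evaluation grid of arc lengths.
#' @slot grid dense evaluation of the curve, length(sGrid) x dim.
#' @slot df smoothing degrees of freedom per coordinate.
#' @slot converged logical.
#' @slot distSq total squared projection distance at convergence.
#' @export
setClass("PrincipalCurve",
  representation(dim = "integer", models = "list", s = "numeric",
                 smax = "numeric", sGrid = "numeric", grid = "matrix",
                 df = "numeric", converged = "logical", distSq = "numeric"))

#' Curvature profile along a fitted curve
#'
#' Signed planar curvature \eqn{\kappa(s) = (x'y'' - x''y')/(x'^2+y'^2)^{3/2}}
#' or non-negative 3D space curvature, evaluated on a curve's arc-length
#' grid.  Values at points of vanishing speed are NA.
#'
#' @slot s arc lengths (mm).
#' @slot kappa curvature values (1/mm).
#' @export
setClass("CurvatureProfile",
  representation(s = "numeric", kappa = "numeric"),
  validity = function(object) {
    if (length(object@s) != length(object@kappa))
      return("s and kappa must have equal length")
    TRUE
  })

#' Change-point scan of a transect signal
#'
#' For each interior grid point s, one-sided first-derivative estimates of
#' depth z(s) from the data below (\code{zb}) and above (\code{za}) s, their
#' linear weight vectors, and the standardized difference
#' \eqn{T(s) = (\hat z_a'(s) - \hat z_b'(s)) / (\sqrt{(w_a-w_b)^T(w_a-w_b)}\,\hat\sigma)}.
#'
#' @slot grid evaluation arc lengths.
#' @slot zaPrime,zbPrime one-sided derivative estimates (NA where masked).
#' @slot se standard errors of the difference.
#' @slot T standardized statistic.
#' @slot sigma noise sd estimate (mm).
#' @export
setClass("ChangepointScan",
  representation(grid = "numeric", zaPrime = "numeric", zbPrime = "numeric",
                 se = "numeric", T = "numeric", sigma = "numeric"))

#' Corresponded semi-landmark grid
#'
#' Ordered 3D points labelled by (transect index, within-transect index);
#' identical descriptors guarantee identical counts and ordering across
#' specimens, giving point-to-point correspondence for shape analysis.
#'
#' @slot points n x 3 coordinates (mm).
#' @slot labels data.frame with columns transect, index.
#' @slot descriptor list describing the construction (k, r, spacing rule...).
#' @export
setClass("SemiLandmarkGrid",
  representation(points = "matrix", labels = "data.frame", descriptor = "list"),
  validity = function(object) {
    if (nrow(object@points) != nrow(object@labels))
      return("labels must match points")
    TRUE
  })

#' Sample of corresponded configurations for shape analysis
#'
#' @slot configs p x 3 x n array of configurations.
#' @slot ids character specimen ids.
#' @slot meta data.frame of per-specimen metadata (n rows).
#' @export
setClass("ShapeSample",
  representation(configs = "array", ids = "character", meta = "data.frame"),
  validity = function(object) {
    d <- dim(object@configs)
    if (length(d) != 3L || d[2] != 3L) return("configs must be p x 3 x n")
    if (length(object@ids) != d[3]) return("ids must match n")
    TRUE
  })

#' Principal component model of shape
#'
#' @slot mean p x 3 mean configuration.
#' @slot loadings 3p x m orthonormal loadings.
#' @slot scores n x m scores (zero column means).
#' @slot sdev component standard deviations (non-increasing).
#' @export
setClass("ShapePCAModel",
  representation(mean = "matrix", loadings = "matrix", scores = "matrix",
                 sdev = "numeric"))
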