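# Penalized B-spline (P-spline) smoothing: the smoothing engine used by the
# principal-curve fitter, the change-point scan and the boundary-curve fits.
# Roughness is controlled by a second-difference penalty on the basis
# coefficients; the amount of smoothing is specified either directly through
# lambda or through effective degrees of freedom (trace of the hat matrix).

# Full knot vector for nbasis B-splines of the given degree over srange,
# equally spaced with degree-fold extension at each end.
.psplineKnots <- function(srange, nbasis, degree = 3L) {
  ninterior <- nbasis - degree + 1L
  if (ninterior < 2L) stop("nbasis too small for degree ", degree)
  inner <- seq(srange[1], srange[2], length.out = ninterior)
  h <- inner[2] - inner[1]
  c(srange[1] - h * (degree:1), inner, srange[2] + h * (1:degree))
}

# Basis (or derivative) matrix; covariate values clamped to the knot span so
# that evaluation at the exact boundary is safe.
.psplineBasis <- function(s, knots, degree = 3L, deriv = 0L) {
  lo <- knots[degree + 1L]
  hi <- knots[length(knots) - degree]
  s <- pmin(pmax(s, lo), hi)
  splines::splineDesign(knots, s, ord = degree + 1L,
                        derivs = rep(deriv, length(s)))
}

.diffOp <- function(nbasis, order) diff(diag(nbasis), differences = order)

# Effective df of the penalized smoother: tr[(B'B + lambda D2'D2)^{-1} B'B].
.psplineEdf <- function(C, P, lambda) {
  sum(diag(solve(C + lambda * P, C)))
}

# Solve lambda so that the achieved df matches the request to +/- 0.05.
# With clustered data C + lambda P can be numerically singular at very
# small lambda; the lower bracket is then walked up until solvable.
.lambdaForDf <- function(C, P, df) {
  nb <- ncol(C)
  df <- min(max(df, 2 + 1e-3), nb - 1e-3)
  f <- function(loglam) .psplineEdf(C, P, 10^loglam) - df
  lo <- -10; hi <- 14
  flo <- tryCatch(f(lo), error = function(e) NULL)
  while (is.null(flo) && lo < hi - 2) {
    lo <- lo + 2
    flo <- tryCatch(f(lo), error = function(e) NULL)
  }
  if (is.null(flo)) stop("penalized system is numerically singular")
  fhi <- tryCatch(f(hi), error = function(e) NULL)
  while (is.null(fhi) && hi > lo + 2) {
    hi <- hi - 2
    fhi <- tryCatch(f(hi), error = function(e) NULL)
  }
  if (is.null(fhi)) stop("penalized system is numerically singular")
  if (flo < 0) return(10^lo)   # even minimal penalty is below target df
  if (fhi > 0) return(10^hi)
  r <- uniroot(f, c(lo, hi), tol = 1e-4)
  10^r$root
}

# Greville abscissae: the covariate location each coefficient acts at.
.greville <- function(knots, degree = 3L) {
  nb <- length(knots) - degree - 1L
  vapply(seq_len(nb), function(j) mean(knots[(j + 1L):(j + degree)]), 0)
}

#' Fit a penalized B-spline regression
#'
#' Minimises \eqn{S(\beta) = (x - B\beta)^T(x - B\beta) +
#' \lambda \beta^T D_2^T D_2 \beta} where the columns of B evaluate cubic
#' B-spline basis functions at the observed covariate values and D2 forms
#' second differences of the coefficients.  The amount of smoothing is given
#' either as \code{lambda} or as effective degrees of freedom \code{df}, in
#' which case lambda is solved so the hat-matrix trace matches to within
#' 0.05.
#'
#' @param s covariate values (arc length, mm).
#' @param x response values.
#' @param nbasis number of basis functions (default 30).
#' @param df target effective degrees of freedom (used when lambda is NULL).
#' @param lambda smoothing parameter; overrides df when given.
#' @param degree spline degree (default cubic).
#' @param srange covariate range spanned by the basis.
#' @return a \linkS4class{PSplineModel}.
#' @examples
#' s <- seq(0, 10, length.out = 80)
#' fit <- fitPspline(s, sin(s) + rnorm(80, sd = 0.05), nbasis = 20, df = 8)
#' plot(s, psplineEval(fit, s), type = "l")
#' @export
fitPspline <- function(s, x, nbasis = 30L, df = NULL, lambda = NULL,
                       degree = 3L, srange = range(s)) {
  stopifnot(length(s) == length(x))
  if (is.null(lambda) && is.null(df)) stop("give df or lambda")
  knots <- .psplineKnots(srange, nbasis, degree)
  B <- .psplineBasis(s, knots, degree)
  C <- crossprod(B)
  D2 <- .diffOp(nbasis, 2L)
  P <- crossprod(D2)
  if (is.null(lambda)) lambda <- .lambdaForDf(C, P, df)
  # augmented least squares: numerically stable down to small lambda; at
  # lambda = 0 the minimum-norm interpolating solution is used
  if (lambda > 0) {
    Baug <- rbind(B, sqrt(lambda) * D2)
    qrB <- qr(Baug)
    if (qrB$rank < nbasis) stop("penalized system is rank deficient")
    beta <- drop(qr.coef(qrB, c(x, numeric(nrow(D2)))))
  } else {
    beta <- drop(MASS::ginv(B) %*% x)
  }
  edf <- if (lambda > 0) .psplineEdf(C, P, lambda) else qr(B)$rank
  new("PSplineModel", knots = knots, degree = as.integer(degree),
      beta = beta, betaUnc = beta, lambda = lambda, kappa = 0,
      df = edf, srange = srange, converged = TRUE)
}

#' Evaluate a fitted P-spline (or a derivative)
#'
#' @param model a \linkS4class{PSplineModel}.
#' @param s covariate values; clamped to the basis span.
#' @param deriv derivative order (0, 1 or 2).
#' @return numeric vector of fitted values.
#' @export
psplineEval <- function(model, s, deriv = 0L) {
  drop(.psplineBasis(s, model@knots, model@degree, deriv) %*% model@beta)
}

#' Constrain a fitted P-spline through given points
#'
#' Adjusts the fitted coefficients so that the curve passes exactly through
#' the constraint points, by the closed-form update
#' \deqn{\hat\beta_c = \hat\beta + M^{-1} A^T [A M^{-1} A^T]^{-1} (c - A\hat\beta)}
#' with \eqn{M = B^T B + \lambda D_2^T D_2} the penalised Gram matrix, A the
#' basis evaluated at the constraint locations and c the target values.
#'
#' @param model a fitted \linkS4class{PSplineModel}.
#' @param at covariate locations of the constraints (e.g. corner arc lengths).
#' @param values target values at those locations.
#' @param s,x the original data (needed to rebuild the Gram matrix).
#' @return the model with constrained coefficients in \code{beta}.
#' @export
constrainThroughPoints <- function(model, at, values, s, x) {
  stopifnot(length(at) == length(values))
  A <- .psplineBasis(at, model@knots, model@degree)
  if (qr(A)$rank < nrow(A)) stop("constraint rows are linearly dependent")
  B <- .psplineBasis(s, model@knots, model@degree)
  nb <- length(model@beta)
  M <- crossprod(B) + model@lambda * crossprod(.diffOp(nb, 2L))
  beta <- .constrainBeta(model@beta, M, A, values)
  model@beta <- beta
  model
}

# Core of Eq.-style equality constraining given a penalised Gram matrix M.
.constrainBeta <- function(beta, M, A, cvec) {
  MiAt <- solve(M, t(A))
  S <- A %*% MiAt
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok) stop("singular bracket matrix in equality constraint")
  drop(beta + MiAt %*% solve(S, cvec - A %*% beta))
}

#' Shape constraint specification for P-spline fitting
#'
#' Describes monotonicity and second-derivative-pattern requirements over
#' fractions of the covariate range.  Each region is a list with elements
#' \code{frac} (two fractions of the range in [0, 1]) and \code{dir}
#' (+1 = increasing, -1 = decreasing).
#'
#' @param monotone list of monotone regions.
#' @param curvature list of second-derivative-pattern regions (dir gives the
#'   required direction of change of the second derivative).
#' @return a list of class \code{shapeSpec}.
#' @export
shapeSpec <- function(monotone = list(), curvature = list()) {
  chk <- function(rs) for (r in rs) {
    stopifnot(length(r$frac) == 2L, r$frac[1] >= 0, r$frac[2] <= 1,
              r$dir %in% c(-1, 1))
  }
  chk(monotone); chk(curvature)
  structure(list(monotone = monotone, curvature = curvature),
            class = "shapeSpec")
}

#' Canonical lip-boundary shape constraints
#'
#' The vertical coordinate of an upper lip boundary is required to increase
#' over the first 40\% of its arc length and decrease over the final 40\%,
#' with its second derivative decreasing then increasing; the lower lip
#' mirrors this (decreasing/increasing, second derivative increasing then
#' decreasing).  The central 20\% is left unconstrained.
#'
#' @param frac half-width of each constrained region as a fraction of arc
#'   length (default 0.4).
#' @return a \code{shapeSpec}.
#' @export
upperLipShape <- function(frac = 0.4) {
  shapeSpec(
    monotone = list(list(frac = c(0, frac), dir = 1),
                    list(frac = c(1 - frac, 1), dir = -1)),
    curvature = list(list(frac = c(0, frac), dir = -1),
                     list(frac = c(1 - frac, 1), dir = 1)))
}

#' @rdname upperLipShape
#' @export
lowerLipShape <- function(frac = 0.4) {
  shapeSpec(
    monotone = list(list(frac = c(0, frac), dir = -1),
                    list(frac = c(1 - frac, 1), dir = 1)),
    curvature = list(list(frac = c(0, frac), dir = 1),
                     list(frac = c(1 - frac, 1), dir = -1)))
}

# Violation masks from the current coefficients.  Positions of first- and
# second-difference rows are taken at Greville abscissae so that "first 40%
# of arc length" maps onto coefficient indices.
.shapeMasks <- function(beta, knots, degree, srange, shapes) {
  nb <- length(beta)
  g <- .greville(knots, degree)
  span <- srange[2] - srange[1]
  inRegion <- function(pos, frac)
    pos >= srange[1] + frac[1] * span & pos <= srange[1] + frac[2] * span
  d1 <- diff(beta)
  pos1 <- (g[-nb] + g[-1]) / 2
  v1 <- numeric(nb - 1L)
  for (r in shapes$monotone)
    v1[inRegion(pos1, r$frac) & r$dir * d1 < 0] <- 1
  d2 <- diff(beta, differences = 2L)
  pos2 <- g[2:(nb - 1L)]
  v2 <- numeric(nb - 2L)
  if (nb >= 4L) {
    ch <- diff(d2)                        # change in the second differences
    posc <- (pos2[-(nb - 2L)] + pos2[-1]) / 2
    for (r in shapes$curvature) {
      bad <- inRegion(posc, r$frac) & r$dir * ch < 0
      v2[c(bad, FALSE) | c(FALSE, bad)] <- 1
    }
  }
  list(v1 = v1, v2 = v2)
}

#' Shape-constrained, point-constrained P-spline fit
#'
#' Minimises \eqn{S(\beta) = \|x - B\beta\|^2 + \lambda\beta^T D_2^T D_2\beta
#' + \kappa\beta^T D_1^T V_1 D_1\beta + \kappa\beta^T D_2^T V_2 D_2\beta}
#' where V1 flags first differences violating the requested monotonicity and
#' V2 flags changes in second differences inconsistent with the requested
#' second-derivative pattern.  Because V1 and V2 depend on the coefficients,
#' the fit iterates mask construction and penalised solving to a fixed point
#' (at most \code{maxIter} rounds).  Equality constraints through given
#' points are re-applied at every round via the closed-form update.  The
#' shape penalties are soft: large \code{kappaFactor} (default 100, giving
#' kappa = 100 lambda) enforces them in large measure but not exactly.
#'
#' @inheritParams fitPspline
#' @param at,values equality-constraint locations and targets (optional).
#' @param shapes a \code{\link{shapeSpec}}.
#' @param kappaFactor kappa as a multiple of lambda (default 100).
#' @param maxIter mask-iteration cap (default 50).
#' @return a \linkS4class{PSplineModel}; \code{converged} is FALSE if the
#'   masks were still changing at the cap.
#' @export
fitShapeConstrained <- function(s, x, nbasis = 30L, df = 25, at = NULL,
                                values = NULL, shapes = shapeSpec(),
                                kappaFactor = 100, maxIter = 50L,
                                degree = 3L, srange = range(s)) {
  knots <- .psplineKnots(srange, nbasis, degree)
  B <- .psplineBasis(s, knots, degree)
  C <- crossprod(B)
  D1 <- .diffOp(nbasis, 1L); D2 <- .diffOp(nbasis, 2L)
  P <- crossprod(D2)
  lambda <- .lambdaForDf(C, P, df)
  kappa <- kappaFactor * lambda
  Btx <- crossprod(B, x)
  A <- if (!is.null(at)) .psplineBasis(at, knots, degree) else NULL
  beta <- drop(solve(C + lambda * P, Btx))
  solveMasked <- function(v1, v2) {
    M <- C + lambda * P +
      kappa * crossprod(D1 * v1) + kappa * crossprod(D2 * v2)
    b <- drop(solve(M, Btx))
    if (!is.null(A)) b <- .constrainBeta(b, M, A, values)
    b
  }
  seen <- character()
  v1 <- v2 <- NULL
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    m <- .shapeMasks(beta, knots, degree, srange, shapes)
    if (!is.null(v1) && identical(m$v1, v1) && identical(m$v2, v2)) {
      converged <- TRUE
      break
    }
    sig <- paste(c(m$v1, m$v2), collapse = "")
    if (sig %in% seen) {
      # mask cycle: penalise the union of the cycling violation sets
      v1 <- pmax(v1, m$v1); v2 <- pmax(v2, m$v2)
      beta <- solveMasked(v1, v2)
      converged <- TRUE
      break
    }
    seen <- c(seen, sig)
    v1 <- m$v1; v2 <- m$v2
    beta <- solveMasked(v1, v2)
  }
  new("PSplineModel", knots = knots, degree = as.integer(degree),
      beta = beta, betaUnc = drop(solve(C + lambda * P, Btx)),
      lambda = lambda, kappa = kappa,
      df = .psplineEdf(C, P, lambda), srange = srange, converged = converged)
}

# Penalised objective for a given mask pair (used by tests asserting descent).
.shapeObjective <- function(beta, B, x, lambda, kappa, v1, v2) {
  nb <- length(beta)
  D1 <- .diffOp(nb, 1L); D2 <- .diffOp(nb, 2L)
  r <- x - drop(B %*% beta)
  sum(r^2) + lambda * sum((D2 %*% beta)^2) +
    kappa * sum(v1 * (D1 %*% beta)^2) + kappa * sum(v2 * (D2 %*% beta)^2)
}

#' Serialise a P-spline model to JSON
#'
#' @param model a \linkS4class{PSplineModel}.
#' @param path output file path.
#' @export
writePSplineJSON <- function(model, path) {
  jsonlite::write_json(list(knots = model@knots, degree = model@degree,
                            lambda = model@lambda, kappa = model@kappa,
                            beta = model@beta),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
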