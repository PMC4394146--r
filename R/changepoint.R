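# Change-point evidence for sharp changes in the first derivative of a
# transect signal z(s) (depth against arc length).  At each grid point two
# one-sided P-spline fits are made — one to the data below s, one to the
# data above — and their first-derivative estimates at s are compared on a
# standard-error scale:
#
#   T(s) = (za'(s) - zb'(s)) / sqrt((wa - wb)'(wa - wb)) sigma_hat
#
# where wa, wb are the linear weight vectors of the two derivative
# estimates and sigma_hat comes from local differencing.  |T| > 5 is taken
# as strong evidence for a ridge/valley crossing.

#' Noise standard deviation by local differencing
#'
#' Difference-based estimate of the residual sd of z against s: each
#' interior observation is compared with the linear interpolation of its two
#' neighbours, and the squared discrepancies are normalised by their
#' variance factor so that iid noise of sd sigma yields expectation sigma
#' (for equal spacing this is the classical second-difference estimator
#' with the 1/6 normalisation).
#'
#' @param s sorted arc lengths (mm).
#' @param z depth values (mm).
#' @return sigma estimate (mm).
#' @export
estimateSigma <- function(s, z) {
  n <- length(s)
  stopifnot(length(z) == n)
  if (n < 3L) stop("need at least 3 points to difference")
  o <- order(s)
  s <- s[o]; z <- z[o]
  i <- 2:(n - 1L)
  w <- (s[i + 1L] - s[i]) / (s[i + 1L] - s[i - 1L])
  r <- w * z[i - 1L] + (1 - w) * z[i + 1L] - z[i]
  fac <- w^2 + (1 - w)^2 + 1
  sqrt(mean(r^2 / fac))
}

# One-sided derivative weight rows for a set of grid points.  For each grid
# point g: fit a P-spline at the requested df to the observations with
# s <= g (below) and s > g (above); the derivative estimate at g is a
# linear functional w'z whose weights are returned as rows of n-column
# matrices (NA rows where a side is insufficient).  Weights depend on s and
# the grid only, so they can be reused across many signals z.
.scanWeights <- function(s, grid, df = 8, nbasis = 12L, degree = 3L) {
  n <- length(s)
  ng <- length(grid)
  Wa <- matrix(NA_real_, ng, n)
  Wb <- matrix(NA_real_, ng, n)
  minPts <- max(ceiling(df) + 2L, degree + 2L)
  sideW <- function(idx, g) {
    ss <- s[idx]
    rng <- range(c(ss, g))
    if (diff(rng) < 1e-9) return(NULL)
    nb <- min(nbasis, max(length(idx) - 1L, degree + 1L))
    if (nb < degree + 1L) return(NULL)
    knots <- .psplineKnots(rng, nb, degree)
    B <- .psplineBasis(ss, knots, degree)
    C <- crossprod(B)
    P <- crossprod(.diffOp(nb, 2L))
    lam <- .lambdaForDf(C, P, min(df, nb - 0.5))
    b1 <- .psplineBasis(g, knots, degree, deriv = 1L)
    drop(b1 %*% solve(C + lam * P, t(B)))
  }
  for (k in seq_len(ng)) {
    g <- grid[k]
    below <- which(s <= g)
    above <- which(s > g)
    if (length(below) >= minPts) {
      w <- tryCatch(sideW(below, g), error = function(e) NULL)
      if (!is.null(w)) { Wb[k, ] <- 0; Wb[k, below] <- w }
    }
    if (length(above) >= minPts) {
      w <- tryCatch(sideW(above, g), error = function(e) NULL)
      if (!is.null(w)) { Wa[k, ] <- 0; Wa[k, above] <- w }
    }
  }
  list(Wa = Wa, Wb = Wb)
}

#' Scan a transect signal for sharp first-derivative changes
#'
#' Computes the standardized derivative-difference statistic T(s) on an
#' evaluation grid (the observed arc lengths thinned to at most
#' \code{gridMax} points, with a masked fraction at each end where the
#' one-sided fits are unstable).  Both one-sided fits use the same P-spline
#' smoother as the principal-curve machinery, at \code{df} degrees of
#' freedom (default 8, the lip-transect value).
#'
#' @param s arc lengths (mm); need not be sorted.
#' @param z depth values (mm).
#' @param df one-sided smoothing degrees of freedom (default 8).
#' @param gridMax maximum evaluation grid size (default 200).
#' @param endMask fraction of the s-range masked at each end (default 0.1).
#' @param design optional precomputed design from \code{\link{scanDesign}}
#'   (reuse across many signals observed at the same arc lengths).
#' @return a \linkS4class{ChangepointScan}.
#' @export
scanDerivativeChange <- function(s, z, df = 8, gridMax = 200L,
                                 endMask = 0.1, design = NULL) {
  n <- length(s)
  stopifnot(length(z) == n)
  if (n < 20L) stop("need at least 20 points, have ", n)
  o <- order(s)
  s <- s[o]; z <- z[o]
  if (is.null(design))
    design <- scanDesign(s, df = df, gridMax = gridMax, endMask = endMask)
  grid <- design$grid
  sigma <- estimateSigma(s, z)
  za <- drop(design$Wa %*% z)
  zb <- drop(design$Wb %*% z)
  se <- design$seUnit * sigma
  Tst <- (za - zb) / se
  bad <- !is.finite(za) | !is.finite(zb) | !is.finite(se) | se <= 0
  Tst[bad] <- NA_real_
  new("ChangepointScan", grid = grid, zaPrime = za, zbPrime = zb,
      se = se, T = Tst, sigma = sigma)
}

#' Precompute the one-sided derivative design for a scan
#'
#' The weight vectors of the one-sided derivative estimates depend only on
#' the observation arc lengths, the evaluation grid and the smoothing df —
#' not on the depth values.  Precomputing them lets many signals sharing a
#' design (e.g. simulation replicates) be scanned by two matrix products.
#'
#' @inheritParams scanDerivativeChange
#' @param grid optional explicit evaluation grid; by default the observed
#'   arc lengths thinned to \code{gridMax} points with masked ends.
#' @return list with \code{grid}, weight matrices \code{Wa}, \code{Wb} and
#'   the unit standard errors \code{seUnit} = ||wa - wb|| per grid point.
#' @export
scanDesign <- function(s, df = 8, gridMax = 200L, endMask = 0.1,
                       grid = NULL) {
  s <- sort(s)
  if (is.null(grid)) {
    rng <- range(s)
    lo <- rng[1] + endMask * diff(rng)
    hi <- rng[2] - endMask * diff(rng)
    gcand <- s[s >= lo & s <= hi]
    if (length(gcand) > gridMax)
      gcand <- gcand[unique(round(seq(1L, length(gcand),
                                      length.out = gridMax)))]
    grid <- unique(gcand)
  }
  w <- .scanWeights(s, grid, df = df)
  dw <- w$Wa - w$Wb
  list(grid = grid, Wa = w$Wa, Wb = w$Wb, seUnit = sqrt(rowSums(dw * dw)))
}

#' Detect a derivative change point
#'
#' Returns the location of the maximum of |T| over the scan grid if it
#' exceeds \code{threshold} (default 5, the evidence level used for midline
#' detection), otherwise NULL — absence of a detection is the scan's way of
#' saying the transect shows no convincing ridge/valley crossing.
#'
#' With the transect convention (arc length running up the face, depth
#' outward), a valley crossing gives a positive derivative jump (T > 0)
#' and a ridge a negative one, so \code{sign} can restrict the search to
#' the feature type of interest (the lip midline is a valley).
#'
#' @param scan a \linkS4class{ChangepointScan}.
#' @param threshold detection threshold on |T| (default 5).
#' @param sign "both" (default), "positive" (valley) or "negative" (ridge).
#' @return list with \code{s} and \code{T} at the maximum, or NULL.
#' @export
detectFeature <- function(scan, threshold = 5,
                          sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  Tv <- switch(sign, both = abs(scan@T), positive = scan@T,
               negative = -scan@T)
  ok <- is.finite(Tv)
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.max(Tv[ok])]
  if (Tv[i] > threshold)
    list(s = scan@grid[i], T = scan@T[i])
  else NULL
}

#' Export a change-point scan as CSV
#'
#' @param scan a \linkS4class{ChangepointScan}.
#' @param path output path.
#' @export
writeScanCSV <- function(scan, path) {
  utils::write.csv(data.frame(s = scan@grid, za_prime = scan@zaPrime,
                              zb_prime = scan@zbPrime, se = scan@se,
                              T = scan@T),
                   path, row.names = FALSE)
  invisible(path)
}
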