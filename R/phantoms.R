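# Synthetic torso and lip phantoms with analytically known ground truth.
# These emulate stereo-photogrammetric surface captures: unstructured
# (jittered-lattice) point sampling, optional iid surface noise and a
# spatially correlated "orange peel" field, at study-scale resolution
# (around 30,000 points for a torso, around 150,000 for a full face patch).

# run expr with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# C2 (quintic) smoothstep: its bends are single interior curvature peaks,
# which keeps the phantom's corner definition unambiguous
.smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^3 * (10 - 15 * t + 6 * t^2)
}

.checkPositive <- function(spec, fields) {
  for (f in fields)
    if (!is.numeric(spec[[f]]) || length(spec[[f]]) != 1L || spec[[f]] <= 0)
      stop("phantom spec field '", f, "' must be a positive number")
}

#' Torso phantom specification
#'
#' Geometry and sampling parameters for \code{\link{makeTorsoPhantom}}.
#' Lengths in mm; \code{density} in points per square mm of the chest
#' parameter plane.  Defaults reproduce a study-scale capture: about
#' 30,000 points over a 500 x 400 mm torso window, giving neighbourhoods
#' of roughly 65 points within a 12 mm radius.
#'
#' @param breastRadius sphere radius of the breast cap (mm).
#' @param boundaryFraction cap base radius as a fraction of breastRadius.
#' @param chestRadius chest-wall cylinder radius (mm).
#' @param moundEccentricity vertical/horizontal mound axis ratio (1 =
#'   circular boundary).
#' @param moundSeparation distance of each mound centre from the midline
#'   (mm).
#' @param filletWidth half-width of the C2 fillet joining cap to chest (mm);
#'   the fillet crest is the ground-truth boundary.
#' @param extentU,extentV half-extents of the sampled window (mm, along the
#'   chest arc and vertically).
#' @param density points per mm^2.
#' @param noiseSD iid surface-normal noise sd (mm).
#' @param orangePeelAmplitude sd of the correlated surface field (mm).
#' @param correlationLength distance at which the orange-peel correlation
#'   falls to exp(-1/2) (mm).
#' @param shoulderRidgeHeight optional pose-induced horizontal ridge above
#'   the breasts (mm; 0 disables).  Its shape is a convention of this
#'   package, used to exercise the candidate-exclusion rules.
#' @param seed integer random seed; fully determines the output.
#' @return a list of class \code{phantomSpec} with \code{kind = "torso"}.
#' @export
torsoSpec <- function(breastRadius = 60, boundaryFraction = 0.75,
                      chestRadius = 200, moundEccentricity = 1,
                      moundSeparation = 90, filletWidth = 5,
                      extentU = 250, extentV = 200, density = 0.15,
                      noiseSD = 0, orangePeelAmplitude = 0,
                      correlationLength = 10, shoulderRidgeHeight = 0,
                      seed = 1L) {
  spec <- list(kind = "torso", breastRadius = breastRadius,
               boundaryFraction = boundaryFraction, chestRadius = chestRadius,
               moundEccentricity = moundEccentricity,
               moundSeparation = moundSeparation, filletWidth = filletWidth,
               extentU = extentU, extentV = extentV, density = density,
               noiseSD = noiseSD, orangePeelAmplitude = orangePeelAmplitude,
               correlationLength = correlationLength,
               shoulderRidgeHeight = shoulderRidgeHeight,
               seed = as.integer(seed))
  .checkPositive(spec, c("breastRadius", "boundaryFraction", "chestRadius",
                         "moundEccentricity", "moundSeparation",
                         "filletWidth", "extentU", "extentV", "density",
                         "correlationLength"))
  if (spec$boundaryFraction >= 1) stop("boundaryFraction must be < 1")
  if (spec$noiseSD < 0 || spec$orangePeelAmplitude < 0)
    stop("phantom spec field 'noiseSD'/'orangePeelAmplitude' must be >= 0")
  class(spec) <- "phantomSpec"
  spec
}

# mound height profile: spherical cap joined to the chest by a C2 quintic
# fillet over [rhoB - w, rhoB + w].  The quintic matches value, slope and
# curvature of the cap at the inner end and is flat at the outer end, so
# its bending is a single interior peak — the crest that defines the
# ground-truth boundary.
.moundProfile <- function(rho, r, rhoB, w) {
  capH <- function(p) sqrt(pmax(r^2 - p^2, 0)) - sqrt(r^2 - rhoB^2)
  capD <- function(p) -p / sqrt(pmax(r^2 - p^2, r^2 * 1e-8))
  capA <- function(p) -r^2 / pmax(r^2 - p^2, r^2 * 1e-8)^1.5
  r1 <- rhoB - w; r2 <- rhoB + w
  h <- numeric(length(rho))
  inCap <- rho <= r1
  h[inCap] <- capH(rho[inCap])
  inF <- rho > r1 & rho < r2
  if (any(inF)) {
    L <- 2 * w
    t <- (rho[inF] - r1) / L
    y1 <- capH(r1); d1 <- capD(r1) * L; a1 <- capA(r1) * L^2
    H0 <- 1 - 10 * t^3 + 15 * t^4 - 6 * t^5
    H1 <- t - 6 * t^3 + 8 * t^4 - 3 * t^5
    H2 <- 0.5 * t^2 - 1.5 * t^3 + 1.5 * t^4 - 0.5 * t^5
    h[inF] <- y1 * H0 + d1 * H1 + a1 * H2    # outer end: value/slope/acc 0
  }
  h
}

# crest of the fillet: the radius of maximum profile curvature
.moundBoundaryRadius <- function(r, rhoB, w) {
  p <- seq(rhoB - 1.5 * w, rhoB + w, length.out = 2001L)
  h <- .moundProfile(p, r, rhoB, w)
  dp <- p[2] - p[1]
  d1 <- (h[c(-1, -2)] - h[1:(length(h) - 2)]) / (2 * dp)
  d2 <- diff(h, differences = 2L) / dp^2
  k <- d2 / (1 + d1^2)^1.5
  p[which.max(k) + 1L]
}

# elliptical parameter-plane distance to a mound centre
.moundRho <- function(u, v, uc, vc, ecc) {
  sqrt((u - uc)^2 + ((v - vc) / ecc)^2)
}

# full torso height field over the chest parameter plane
.torsoHeight <- function(u, v, spec) {
  r <- spec$breastRadius
  rhoB <- spec$boundaryFraction * r
  w <- spec$filletWidth
  h <- .moundProfile(.moundRho(u, v, spec$moundSeparation, 0,
                               spec$moundEccentricity), r, rhoB, w) +
       .moundProfile(.moundRho(u, v, -spec$moundSeparation, 0,
                               spec$moundEccentricity), r, rhoB, w)
  if (spec$shoulderRidgeHeight > 0)
    h <- h + spec$shoulderRidgeHeight * exp(-(v - 150)^2 / (2 * 8^2))
  h
}

# chest parameter plane -> 3D (cylindrical chest wall, x outward, z up)
.torsoMap <- function(u, v, spec) {
  Rc <- spec$chestRadius
  h <- .torsoHeight(u, v, spec)
  th <- u / Rc
  cbind(x = (Rc + h) * cos(th) - Rc,
        y = (Rc + h) * sin(th),
        z = v)
}

.mapNormals <- function(u, v, mapFun, eps = 1e-3) {
  Fu <- (mapFun(u + eps, v) - mapFun(u - eps, v)) / (2 * eps)
  Fv <- (mapFun(u, v + eps) - mapFun(u, v - eps)) / (2 * eps)
  N <- cbind(Fu[, 2] * Fv[, 3] - Fu[, 3] * Fv[, 2],
             Fu[, 3] * Fv[, 1] - Fu[, 1] * Fv[, 3],
             Fu[, 1] * Fv[, 2] - Fu[, 2] * Fv[, 1])
  N / sqrt(rowSums(N^2))
}

# jittered-lattice sampling of a rectangle (deterministic given the RNG)
.jitterLattice <- function(halfU, halfV, density) {
  a <- 1 / sqrt(density)
  nu <- max(2L, floor(2 * halfU / a))
  nv <- max(2L, floor(2 * halfV / a))
  gu <- seq(-halfU + a / 2, by = a, length.out = nu)
  gv <- seq(-halfV + a / 2, by = a, length.out = nv)
  u <- rep(gu, times = nv) + runif(nu * nv, -a / 2, a / 2)
  v <- rep(gv, each = nu) + runif(nu * nv, -a / 2, a / 2)
  cbind(u = u, v = v)
}

#' Generate a torso phantom
#'
#' Builds a chest wall with two breast mounds, named landmarks and the
#' ground-truth boundary curves (the crests of the cap-to-chest fillets).
#' Landmarks are suffixed by side (\code{prom_R}, \code{med_R}, ...);
#' \code{ssn} and \code{xipho} sit on the midline.  Use
#' \code{\link{sideLandmarks}} to obtain the canonical per-breast names the
#' pipeline expects.
#'
#' @param spec a \code{\link{torsoSpec}}.
#' @return list with elements \code{cloud} (\linkS4class{SurfacePointCloud}),
#'   \code{landmarks} (\linkS4class{LandmarkSet}) and \code{truth} (list
#'   with per-side boundary polylines \code{boundaries$R/L}, the boundary
#'   radius \code{rhoStar} and the landmark set).
#' @examples
#' ph <- makeTorsoPhantom(torsoSpec(density = 0.05, seed = 7))
#' ph$cloud
#' @export
makeTorsoPhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  if (spec$kind != "torso") stop("spec must have kind 'torso'")
  r <- spec$breastRadius
  rhoB <- spec$boundaryFraction * r
  rhoStar <- .moundBoundaryRadius(r, rhoB, spec$filletWidth)
  mapFun <- function(u, v) .torsoMap(u, v, spec)

  .withSeed(spec$seed, {
    uv <- .jitterLattice(spec$extentU, spec$extentV, spec$density)
    P <- mapFun(uv[, 1], uv[, 2])
    N <- .mapNormals(uv[, 1], uv[, 2], mapFun)
    cloud <- SurfacePointCloud(P, normals = N)
    if (spec$noiseSD > 0 || spec$orangePeelAmplitude > 0)
      cloud <- addSurfaceNoise(cloud, sd = spec$noiseSD,
                               orangePeelAmplitude = spec$orangePeelAmplitude,
                               correlationLength = spec$correlationLength,
                               seed = spec$seed + 1L)
    cloud
  }) -> cloud

  ecc <- spec$moundEccentricity
  sep <- spec$moundSeparation
  boundaryCurve <- function(uc) {
    phi <- seq(0, 2 * pi, length.out = 721L)
    mapFun(uc + rhoStar * cos(phi), ecc * rhoStar * sin(phi))
  }
  lmOne <- function(uc, side) {
    m <- rbind(prom = c(uc, 0),
               med = c(uc - sign(uc) * rhoStar, 0),
               lat = c(uc + sign(uc) * rhoStar, 0),
               inf = c(uc, -ecc * rhoStar))
    out <- mapFun(m[, 1], m[, 2])
    rownames(out) <- paste0(rownames(m), "_", side)
    out
  }
  lm <- rbind(lmOne(sep, "R"), lmOne(-sep, "L"),
              ssn = mapFun(0, 120)[1, ], xipho = mapFun(0, -80)[1, ])
  landmarks <- LandmarkSet(lm)
  truth <- list(boundaries = list(R = boundaryCurve(sep),
                                  L = boundaryCurve(-sep)),
                rhoStar = rhoStar, landmarks = landmarks)
  list(cloud = cloud, landmarks = landmarks, truth = truth)
}

#' Canonical per-breast landmark subset
#'
#' Maps side-suffixed torso landmarks (\code{prom_R}, ...) to the canonical
#' names \code{prom, med, lat, inf} expected by the breast pipeline, keeping
#' the midline landmarks \code{ssn} and \code{xipho}.
#'
#' @param landmarks a torso \linkS4class{LandmarkSet}.
#' @param side "R" or "L".
#' @return a \linkS4class{LandmarkSet}.
#' @export
sideLandmarks <- function(landmarks, side = c("R", "L")) {
  side <- match.arg(side)
  nm <- c("prom", "med", "lat", "inf")
  cc <- rbind(landmarks@coords[paste0(nm, "_", side), , drop = FALSE],
              landmarks@coords[c("ssn", "xipho"), , drop = FALSE])
  rownames(cc) <- c(nm, "ssn", "xipho")
  LandmarkSet(cc)
}

#' Lip phantom specification
#'
#' Parameters for \code{\link{makeLipPhantom}}: a gently curved skin patch
#' carrying an upper and a lower lip ridge and a sharp intervening valley
#' (the closed-mouth midline), all meeting at two mouth corners.  Defaults
#' sample the mouth region at full-face stereo-photogrammetry resolution;
#' \code{highDensity = TRUE} switches to a face-sized patch of around
#' 150,000 points.
#'
#' @param mouthHalfWidth nominal half-width of the mouth (mm); the true
#'   corners sit at the curvature maxima of the midline curve, slightly
#'   inside this.
#' @param upperRidgeHeight,lowerRidgeHeight ridge heights (mm); 0 removes
#'   that ridge (its ground-truth curve is then flagged absent).
#' @param valleyDepth depth of the midline valley (mm).
#' @param upperRidgeOffset,lowerRidgeOffset vertical distance of each ridge
#'   crest from the midline at the mouth centre (mm).
#' @param ridgeSigma Gaussian cross-section sd of the ridges (mm).
#' @param valleyHalfWidth half-width of the triangular valley profile (mm).
#' @param cornerWidth width of the smooth rise of the valley floor at the
#'   corners (mm); sets how sharply the midline curve bends there.
#' @param commissureDepth residual depth of the commissure crease just
#'   beyond the corners (mm); keeps the midline detectable slightly past
#'   the mouth so the corner bends are interior to the detected curve.
#' @param commissureLength Gaussian fade length of the commissure crease
#'   (mm).
#' @param commissureSlope upward in-plane slope of the commissure crease
#'   beyond the corners (dimensionless); the direction change of the
#'   crease path at the corner is the main corner-curvature signal, as on
#'   real faces.
#' @param notchDepth central dip of the upper ridge line (cupid's-bow
#'   notch, mm; 0 disables).
#' @param faceRadiusX,faceRadiusY radii of the background skin curvature
#'   (mm).
#' @param extentX,extentY half-extents of the sampled patch (mm).
#' @param density points per mm^2 (default full-face resolution).
#' @param highDensity logical; face-sized patch of around 150,000 points.
#' @inheritParams torsoSpec
#' @return a list of class \code{phantomSpec} with \code{kind = "lip"}.
#' @export
lipSpec <- function(mouthHalfWidth = 25, upperRidgeHeight = 3,
                    lowerRidgeHeight = 2.5, valleyDepth = 1.5,
                    upperRidgeOffset = 9, lowerRidgeOffset = 10,
                    ridgeSigma = 3, valleyHalfWidth = 3,
                    cornerWidth = 6, commissureDepth = 0.8,
                    commissureLength = 12, commissureSlope = 0.6,
                    notchDepth = 0,
                    faceRadiusX = 120, faceRadiusY = 250,
                    extentX = 45, extentY = 20,
                    density = 150000 / (180 * 200), highDensity = FALSE,
                    noiseSD = 0.05, orangePeelAmplitude = 0,
                    correlationLength = 6, seed = 1L) {
  if (isTRUE(highDensity)) { extentX <- 90; extentY <- 100 }
  spec <- list(kind = "lip", mouthHalfWidth = mouthHalfWidth,
               upperRidgeHeight = upperRidgeHeight,
               lowerRidgeHeight = lowerRidgeHeight,
               valleyDepth = valleyDepth,
               upperRidgeOffset = upperRidgeOffset,
               lowerRidgeOffset = lowerRidgeOffset,
               ridgeSigma = ridgeSigma, valleyHalfWidth = valleyHalfWidth,
               cornerWidth = cornerWidth, commissureDepth = commissureDepth,
               commissureLength = commissureLength,
               commissureSlope = commissureSlope, notchDepth = notchDepth,
               faceRadiusX = faceRadiusX, faceRadiusY = faceRadiusY,
               extentX = extentX, extentY = extentY, density = density,
               highDensity = isTRUE(highDensity),
               noiseSD = noiseSD, orangePeelAmplitude = orangePeelAmplitude,
               correlationLength = correlationLength, seed = as.integer(seed))
  .checkPositive(spec, c("mouthHalfWidth", "valleyDepth", "upperRidgeOffset",
                         "lowerRidgeOffset", "ridgeSigma", "valleyHalfWidth",
                         "cornerWidth", "faceRadiusX", "faceRadiusY",
                         "extentX", "extentY", "density",
                         "correlationLength"))
  if (spec$upperRidgeHeight < 0 || spec$lowerRidgeHeight < 0 ||
      spec$notchDepth < 0 || spec$noiseSD < 0 ||
      spec$orangePeelAmplitude < 0)
    stop("phantom spec heights/noise must be >= 0")
  class(spec) <- "phantomSpec"
  spec
}

# valley floor profile along x: -valleyDepth inside the mouth, rising
# sharply at the corners to a shallow commissure crease that fades as a
# smooth Gaussian further laterally (as the labial commissure does on real
# faces).  The fade is curvature-free to first order, so the corner bends
# remain the only strong curvature maxima of the midline curve.
.lipValleyFloor <- function(x, spec) {
  dm <- spec$valleyDepth - spec$commissureDepth
  -dm * .smoothstep((spec$mouthHalfWidth - abs(x)) / spec$cornerWidth) -
    spec$commissureDepth *
      exp(-((abs(x) - spec$mouthHalfWidth) / spec$commissureLength)^2 / 2)
}

# centre line of the valley crease: flat (y = 0) across the mouth, turning
# upward past the corners with a smooth (softplus) bend — the in-plane
# direction change that marks the commissure on real faces
.lipValleyPath <- function(x, spec) {
  wb <- spec$cornerWidth / 4
  spec$commissureSlope * wb * log1p(exp((abs(x) - spec$mouthHalfWidth) / wb))
}

# ridge centre lines over [-xk, xk], measured from the valley path so the
# three curves meet at the corners
.lipRidgeCentre <- function(x, xk, offset, notch = 0) {
  y <- offset * (1 - (x / xk)^2)
  if (notch > 0) y <- y - notch * exp(-x^2 / (2 * 3^2)) * (abs(x) < xk)
  y
}

# the full lip depth field z(x, y)
.lipHeight <- function(x, y, spec, xk) {
  ym <- .lipValleyPath(x, spec)
  z <- -x^2 / (2 * spec$faceRadiusX) - y^2 / (2 * spec$faceRadiusY)
  z <- z + .lipValleyFloor(x, spec) *
    pmax(0, 1 - abs(y - ym) / spec$valleyHalfWidth)
  inM <- abs(x) < xk
  amp <- ifelse(inM, 1 - (x / xk)^2, 0)
  if (spec$upperRidgeHeight > 0) {
    yu <- ym + ifelse(inM, .lipRidgeCentre(x, xk, spec$upperRidgeOffset,
                                           spec$notchDepth), 0)
    z <- z + spec$upperRidgeHeight * amp *
      exp(-(y - yu)^2 / (2 * spec$ridgeSigma^2))
  }
  if (spec$lowerRidgeHeight > 0) {
    yl <- ym - ifelse(inM, .lipRidgeCentre(x, xk, spec$lowerRidgeOffset), 0)
    z <- z + spec$lowerRidgeHeight * amp *
      exp(-(y - yl)^2 / (2 * spec$ridgeSigma^2))
  }
  z
}

# 3D curvature of a polyline by finite differences
.polylineKappa <- function(P, h) {
  n <- nrow(P)
  d1 <- (P[3:n, ] - P[1:(n - 2), ]) / (2 * h)
  d2 <- (P[3:n, ] - 2 * P[2:(n - 1), ] + P[1:(n - 2), ]) / h^2
  num <- sqrt((d2[, 1] * d1[, 2] - d2[, 2] * d1[, 1])^2 +
              (d2[, 1] * d1[, 3] - d2[, 3] * d1[, 1])^2 +
              (d2[, 2] * d1[, 3] - d2[, 3] * d1[, 2])^2)
  c(0, num / rowSums(d1^2)^1.5, 0)
}

# the true midline curve of the crease (valley centre path on the surface)
.lipMidlinePolyline <- function(x, spec) {
  ym <- .lipValleyPath(x, spec)
  z <- -x^2 / (2 * spec$faceRadiusX) - ym^2 / (2 * spec$faceRadiusY) +
    .lipValleyFloor(x, spec)
  cbind(x = x, y = ym, z = z)
}

# corner x-position: the outermost strong 3D curvature maximum of the true
# midline curve, computed on the right half; the left corner is its exact
# mirror image
.lipCornerX <- function(spec) {
  xc <- spec$mouthHalfWidth
  x <- seq(0, xc + 3 * spec$cornerWidth, length.out = 4001L)
  P <- .lipMidlinePolyline(x, spec)
  k <- .polylineKappa(P, x[2] - x[1])
  cand <- which(diff(sign(diff(k))) < 0) + 1L
  cand <- cand[x[cand] > xc - 2 * spec$cornerWidth & k[cand] > 10 / xc^2]
  if (!length(cand)) stop("no corner curvature maximum found")
  x[cand[which.max(k[cand])]]
}

#' Generate a lip phantom
#'
#' Builds a skin patch with an upper ridge, a lower ridge and a sharp
#' intervening valley meeting at two mouth corners, plus seven lip
#' landmarks (cheilion_l/r at the corners; labiale_superius,
#' crista_philtri_l/r on the upper curve; labiale_inferius on the lower;
#' stomion on the midline) and ground-truth curves.
#'
#' @param spec a \code{\link{lipSpec}}.
#' @return list with \code{cloud}, \code{landmarks} and \code{truth}; the
#'   truth holds dense polylines \code{upper}, \code{midline}, \code{lower}
#'   (NULL when the corresponding ridge height is 0, with a matching
#'   \code{present} flag), corner coordinates \code{corners} (2 x 3) and
#'   the corner x-position \code{cornerX}.
#' @export
makeLipPhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  if (spec$kind != "lip") stop("spec must have kind 'lip'")
  xk <- .lipCornerX(spec)
  mapFun <- function(x, y) cbind(x = x, y = y,
                                 z = .lipHeight(x, y, spec, xk))

  .withSeed(spec$seed, {
    xy <- .jitterLattice(spec$extentX, spec$extentY, spec$density)
    P <- mapFun(xy[, 1], xy[, 2])
    N <- .mapNormals(xy[, 1], xy[, 2], mapFun)
    cloud <- SurfacePointCloud(P, normals = N)
    if (spec$noiseSD > 0 || spec$orangePeelAmplitude > 0)
      cloud <- addSurfaceNoise(cloud, sd = spec$noiseSD,
                               orangePeelAmplitude = spec$orangePeelAmplitude,
                               correlationLength = spec$correlationLength,
                               seed = spec$seed + 1L)
    cloud
  }) -> cloud

  xs <- seq(-xk, xk, length.out = 501L)
  ymf <- function(x) .lipValleyPath(x, spec)
  midline <- mapFun(xs, ymf(xs))
  upper <- lower <- NULL
  if (spec$upperRidgeHeight > 0)
    upper <- mapFun(xs, ymf(xs) + .lipRidgeCentre(xs, xk,
                                                  spec$upperRidgeOffset,
                                                  spec$notchDepth))
  if (spec$lowerRidgeHeight > 0)
    lower <- mapFun(xs, ymf(xs) - .lipRidgeCentre(xs, xk,
                                                  spec$lowerRidgeOffset))
  corners <- mapFun(c(-xk, xk), ymf(c(-xk, xk)))
  rownames(corners) <- c("L", "R")

  lmAt <- function(x, y) mapFun(x, y)[1, ]
  yu <- function(x) ymf(x) + .lipRidgeCentre(x, xk, spec$upperRidgeOffset,
                                             spec$notchDepth)
  yl <- function(x) ymf(x) - .lipRidgeCentre(x, xk, spec$lowerRidgeOffset)
  lm <- rbind(cheilion_l = corners["L", ],
              cheilion_r = corners["R", ],
              labiale_superius = lmAt(0, yu(0)),
              crista_philtri_l = lmAt(-6, yu(-6)),
              crista_philtri_r = lmAt(6, yu(6)),
              labiale_inferius = lmAt(0, yl(0)),
              stomion = lmAt(0, ymf(0)))
  landmarks <- LandmarkSet(lm)
  truth <- list(upper = upper, midline = midline, lower = lower,
                present = c(upper = spec$upperRidgeHeight > 0,
                            midline = TRUE,
                            lower = spec$lowerRidgeHeight > 0),
                corners = corners, cornerX = xk, landmarks = landmarks)
  list(cloud = cloud, landmarks = landmarks, truth = truth)
}

# normal estimation by neighbourhood PCA with a cell-hash search
.estimateNormals <- function(P, radius = NULL) {
  n <- nrow(P)
  if (is.null(radius)) {
    rg <- apply(P, 2, function(v) diff(range(v)))
    area <- prod(sort(rg, decreasing = TRUE)[1:2])
    radius <- 3 * sqrt(area / n)
  }
  cell <- floor(sweep(P, 2, apply(P, 2, min)) / radius)
  key <- cell[, 1] + 1e4 * (cell[, 2] + 1e4 * cell[, 3])
  byCell <- split(seq_len(n), key)
  lookup <- new.env(hash = TRUE, size = length(byCell))
  for (k in names(byCell)) assign(k, byCell[[k]], envir = lookup)
  ctr <- colMeans(P)
  N <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    nb <- integer()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- as.character((cell[i, 1] + dx) + 1e4 *
                        ((cell[i, 2] + dy) + 1e4 * (cell[i, 3] + dz)))
      v <- lookup[[k]]
      if (!is.null(v)) nb <- c(nb, v)
    }
    if (length(nb) > 40L) nb <- nb[seq(1L, length(nb), length.out = 40L)]
    if (length(nb) < 4L) { N[i, ] <- c(0, 0, 1); next }
    ev <- eigen(stats::cov(P[nb, , drop = FALSE]), symmetric = TRUE)
    v <- ev$vectors[, 3L]
    if (sum(v * (P[i, ] - ctr)) < 0) v <- -v
    N[i, ] <- v
  }
  N
}

#' Add surface noise to a point cloud
#'
#' Displaces every point along its surface normal by iid Gaussian noise of
#' sd \code{sd} plus a smooth spatially correlated field (the "orange peel"
#' reconstruction artefact): a Gaussian random field built from randomly
#' weighted Gaussian kernels, standardised so its sample sd equals
#' \code{orangePeelAmplitude} and its correlation falls to exp(-1/2) at
#' \code{correlationLength}.  Uses stored normals when present, otherwise
#' estimates them by neighbourhood PCA.  Deterministic given \code{seed};
#' with both magnitudes 0 the input is returned unchanged.
#'
#' @param cloud a \linkS4class{SurfacePointCloud}.
#' @param sd iid displacement sd (mm), >= 0.
#' @param orangePeelAmplitude correlated-field sd (mm), >= 0.
#' @param correlationLength field correlation length (mm).
#' @param seed integer random seed.
#' @param nCenters number of kernel centres for the correlated field.
#' @return the displaced \linkS4class{SurfacePointCloud}.
#' @export
addSurfaceNoise <- function(cloud, sd = 0, orangePeelAmplitude = 0,
                            correlationLength = 10, seed = 1L,
                            nCenters = 500L) {
  if (sd < 0 || orangePeelAmplitude < 0)
    stop("sd and orangePeelAmplitude must be non-negative")
  if (sd == 0 && orangePeelAmplitude == 0) return(cloud)
  P <- coords(cloud)
  n <- nrow(P)
  N <- if (nrow(cloud@normals) == n) cloud@normals else .estimateNormals(P)
  .withSeed(seed, {
    disp <- if (sd > 0) stats::rnorm(n, sd = sd) else numeric(n)
    if (orangePeelAmplitude > 0) {
      m <- min(nCenters, n)
      ctrIdx <- sample.int(n, m)
      a <- stats::rnorm(m)
      ell <- correlationLength / sqrt(2)
      field <- numeric(n)
      Cc <- P[ctrIdx, , drop = FALSE]
      for (j in seq_len(m)) {
        d2 <- (P[, 1] - Cc[j, 1])^2 + (P[, 2] - Cc[j, 2])^2 +
              (P[, 3] - Cc[j, 3])^2
        field <- field + a[j] * exp(-d2 / (2 * ell^2))
      }
      field <- field / stats::sd(field) * orangePeelAmplitude
      disp <- disp + field
    }
    SurfacePointCloud(P + disp * N, normals = N,
                      colours = if (nrow(cloud@colours)) cloud@colours)
  })
}
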