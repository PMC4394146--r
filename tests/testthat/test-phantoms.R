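test_that("torso phantom is deterministic and at study-scale density", {
  ph1 <- makeTorsoPhantom(torsoSpec(seed = 7L, density = 0.05))
  ph2 <- makeTorsoPhantom(torsoSpec(seed = 7L, density = 0.05))
  expect_identical(coords(ph1$cloud), coords(ph2$cloud))
  ph3 <- makeTorsoPhantom(torsoSpec(seed = 8L, density = 0.05))
  expect_false(identical(coords(ph1$cloud), coords(ph3$cloud)))

  n <- length(torsoPhantom()$cloud)
  expect_gt(n, 0.8 * 30000)
  expect_lt(n, 1.2 * 30000)
})

test_that("invalid phantom specs are rejected with the field named", {
  expect_error(torsoSpec(breastRadius = -5), "breastRadius")
  expect_error(torsoSpec(density = 0), "density")
  expect_error(lipSpec(valleyDepth = -1), "valleyDepth")
  expect_error(torsoSpec(noiseSD = -0.1), "noiseSD")
})

test_that("torso ground truth lies in the sampled cloud", {
  ph <- torsoPhantom()
  P <- coords(ph$cloud)
  a <- 1 / sqrt(0.15)                    # lattice spacing at default density
  bp <- ph$truth$boundaries$R[seq(1, 721, by = 36), ]
  dmin <- apply(bp, 1, function(b) sqrt(min(colSums((t(P) - b)^2))))
  expect_lt(max(dmin), a)

  # landmarks lie on the analytic surface: within half the point spacing
  lm <- coords(ph$landmarks)
  dlm <- apply(lm, 1, function(b) sqrt(min(colSums((t(P) - b)^2))))
  expect_lt(max(dlm), a)
})

test_that("the 12 mm neighbourhood at prom holds tens of points", {
  ph <- torsoPhantom()
  prom <- landmark(ph$landmarks, "prom_R")
  n <- sum(rowSums(sweep(coords(ph$cloud), 2, prom)^2) <= 12^2)
  expect_gt(n, 20)
  expect_lt(n, 200)
})

test_that("noiseless transect curvature peaks at the true boundary", {
  ph <- torsoPhantom()
  lmR <- sideLandmarks(ph$landmarks, "R")
  prom <- landmark(lmR, "prom")
  fr <- localFrame(ph$cloud, prom, 12,
                   refDirection = landmark(lmR, "lat") - prom)
  st <- planarStrip(ph$cloud, fr, delta = 1, half = TRUE, maxAbscissa = 80)
  crv <- stripCurve(st, df = 6)
  mx <- localCurvatureMaxima(planarCurvature(crv), requirePositive = TRUE)
  expect_gt(nrow(mx), 0)
  i <- which.max(mx$kappa)
  fp <- evalCurve(crv, mx$s[i])
  p3 <- ancurve:::.stripTo3D(st, fp[, 1], fp[, 2])
  expect_lt(polylineDistance(p3, ph$truth$boundaries$R), 2)
})

test_that("lip phantom geometry: symmetry, absence flags, density", {
  ph <- lipPhantom()
  expect_equal(ph$truth$corners["L", 1], -ph$truth$corners["R", 1],
               tolerance = 1e-9)
  expect_equal(ph$truth$corners["L", 2:3], ph$truth$corners["R", 2:3],
               tolerance = 1e-9)
  expect_true(all(ph$truth$present))
  expect_equal(nrow(coords(ph$landmarks)), 7L)

  flat <- makeLipPhantom(lipSpec(seed = 2L, upperRidgeHeight = 0,
                                 lowerRidgeHeight = 0, density = 0.5))
  expect_null(flat$truth$upper)
  expect_null(flat$truth$lower)
  expect_false(flat$truth$present["upper"])
  expect_true(flat$truth$present["midline"])

  nh <- nrow(ancurve:::.jitterLattice(90, 100, 150000 / (180 * 200)))
  expect_gt(nh, 0.8 * 150000)
  expect_lt(nh, 1.2 * 150000)
})

test_that("lip ground-truth curves meet pairwise at the corners", {
  ph <- lipPhantom()
  for (nm in c("upper", "midline", "lower")) {
    cv <- ph$truth[[nm]]
    expect_lt(sqrt(sum((cv[1, ] - ph$truth$corners["L", ])^2)), 1e-9)
    expect_lt(sqrt(sum((cv[nrow(cv), ] - ph$truth$corners["R", ])^2)), 1e-9)
  }
})

test_that("surface noise has the requested magnitude and identity at zero", {
  ph <- makeTorsoPhantom(torsoSpec(seed = 3L, density = 0.05))
  expect_identical(addSurfaceNoise(ph$cloud, sd = 0, orangePeelAmplitude = 0),
                   ph$cloud)

  noisy <- addSurfaceNoise(ph$cloud, sd = 0.3, seed = 11L)
  disp <- rowSums((coords(noisy) - coords(ph$cloud)) * ph$cloud@normals)
  expect_lt(abs(sd(disp) / 0.3 - 1), 0.05)

  expect_error(addSurfaceNoise(ph$cloud, sd = -1), "non-negative")

  # determinism
  noisy2 <- addSurfaceNoise(ph$cloud, sd = 0.3, seed = 11L)
  expect_identical(coords(noisy), coords(noisy2))
})

test_that("orange-peel noise has the requested correlation length", {
  ph <- makeTorsoPhantom(torsoSpec(seed = 4L, density = 0.08))
  L <- 12
  noisy <- addSurfaceNoise(ph$cloud, sd = 0, orangePeelAmplitude = 0.5,
                           correlationLength = L, seed = 9L)
  disp <- rowSums((coords(noisy) - coords(ph$cloud)) * ph$cloud@normals)
  P <- coords(ph$cloud)
  set.seed(1)
  i <- sample(length(disp), 4000)
  j <- sample(length(disp), 4000)
  d <- sqrt(rowSums((P[i, ] - P[j, ])^2))
  f <- disp[i] * disp[j]
  v <- var(disp)
  # empirical correlation in distance bins; find the exp(-1/2) crossing
  bins <- cut(d, breaks = seq(0, 40, by = 4))
  corr <- tapply(f, bins, mean) / v
  mids <- seq(2, 38, by = 4)
  below <- which(corr < exp(-0.5))[1]
  est <- approx(corr[c(below - 1, below)], mids[c(below - 1, below)],
                xout = exp(-0.5))$y
  expect_lt(abs(est / L - 1), 0.25)
})
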