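test_that("radial transects honour the midline plane and length caps", {
  ph <- torsoPhantom()
  lmR <- sideLandmarks(ph$landmarks, "R")
  strips <- radialTransects(ph$cloud, lmR, nTransects = 12, delta = 1)
  expect_length(strips, 12L)
  plane <- ancurve:::.midlinePlane(ph$cloud, lmR)
  for (st in strips) {
    if (!nrow(coords(st))) next
    sgn <- drop(sweep(coords(st), 2, plane$point) %*% plane$normal) *
      plane$promSign
    expect_true(all(sgn > 0))
  }
  capped <- radialTransects(ph$cloud, lmR, nTransects = 12, delta = 1,
                            maxLengths = rep(40, 12))
  for (st in capped)
    if (nrow(coords(st))) expect_lte(max(stripCoords(st)[, 1]), 40)
  expect_error(radialTransects(ph$cloud, lmR, nTransects = 4), "at least 8")
})

test_that("curvature candidates locate the cap-plane junction", {
  cl <- capOnPlane()
  apex <- c(0, 0, max(coords(cl)[, 3]))
  fr <- localFrame(cl, apex, radius = 12, refDirection = c(1, 0, 0))
  st <- planarStrip(cl, fr, delta = 1, half = TRUE, maxAbscissa = 60)
  cd <- candidateBoundaryPoints(list(st))[[1]]
  expect_gt(nrow(cd), 0)
  best <- cd[which.max(cd$kappa), ]
  # the junction circle has radius 30 in the plane z = 0
  expect_lt(abs(sqrt(best$x^2 + best$y^2) - 30), 2)
  expect_lt(abs(best$z), 2)

  # a flat strip yields no candidates
  flat <- SurfacePointCloud(cbind(runif(3000, -50, 50),
                                  runif(3000, -50, 50), 0))
  frf <- new("LocalFrame", origin = c(0, 0, 0), axes = diag(3))
  stf <- planarStrip(flat, frf, delta = 1, half = TRUE)
  expect_equal(nrow(candidateBoundaryPoints(list(stf))[[1]]), 0L)
})

test_that("exclusion rules (a)-(c) act on constructed candidates", {
  ph <- torsoPhantom()
  lmR <- sideLandmarks(ph$landmarks, "R")
  med <- landmark(lmR, "med"); lat <- landmark(lmR, "lat")
  prom <- landmark(lmR, "prom")
  plane <- ancurve:::.midlinePlane(ph$cloud, lmR)

  # too close to prom: rule (a)
  dmin <- min(sqrt(sum((med - prom)^2)), sqrt(sum((lat - prom)^2)))
  near <- prom + 0.5 * dmin * ancurve:::.unit(med - prom)
  k1 <- filterCandidates(rbind(near), lmR, ph$cloud)
  expect_false(k1[1])
  expect_equal(attr(k1, "rule")[1], "a")

  # med itself satisfies everything
  k2 <- filterCandidates(rbind(med), lmR, ph$cloud)
  expect_true(k2[1])

  # 20 mm outward along n beyond the med/lat protrusion: rule (b)
  far <- med + 21 * plane$nAvg
  k3 <- filterCandidates(rbind(far), lmR, ph$cloud)
  expect_false(k3[1])
  expect_equal(attr(k3, "rule")[1], "b")

  # far above ssn in elevation: rule (c)
  high <- med + 120 * plane$m
  k4 <- filterCandidates(rbind(high), lmR, ph$cloud, tolerance = 10)
  expect_false(k4[1])

  lmBad <- LandmarkSet(coords(lmR)[-2, , drop = FALSE])
  expect_error(filterCandidates(rbind(med), lmBad, ph$cloud), "med")
})

test_that("gap interpolation uses the prescribed weights", {
  k <- 20
  angles <- 2 * pi * (0:(k - 1)) / k
  # constant sides: all interpolated points equal that constant
  pts <- matrix(rep(c(3, -1, 2), each = k), k, 3)
  pts[8:10, ] <- NA
  out <- interpolateGaps(pts, angles)
  expect_equal(out$points[8:10, ], matrix(rep(c(3, -1, 2), each = 3), 3, 3),
               tolerance = 1e-6)
  expect_equal(which(out$interpolated), 8:10)

  # l = 1: midpoint of the two side predictions (linear data -> exact)
  lin <- cbind(sin(angles), cos(angles), angles / 10)
  lin[5, ] <- NA
  out2 <- interpolateGaps(lin, angles)
  ref <- cbind(sin(angles[5]), cos(angles[5]), angles[5] / 10)
  expect_lt(max(abs(out2$points[5, ] - ref)), 0.1)

  # weights sum to one for every gap position
  l <- 4; i <- seq_len(l)
  expect_equal((l + 1 - i) / (l + 1) + i / (l + 1), rep(1, l))

  # a gap over half the transects is unidentifiable
  bad <- pts; bad[1:11, ] <- NA
  expect_error(interpolateGaps(bad, angles), "half")
})

test_that("closed boundary fitting recovers a circle and closes", {
  k <- 51
  angles <- 2 * pi * (0:(k - 1)) / k
  circ <- cbind(40 * cos(angles), 40 * sin(angles), rep(5, k))
  b <- fitBoundary(circ, angles, df = 12)
  expect_lt(max(abs(sqrt(rowSums(b@grid[, 1:2]^2)) - 40)), 0.5)
  expect_lt(max(abs(b@grid[, 3] - 5)), 0.5)
  closure <- sqrt(sum((b@grid[1, ] - b@grid[nrow(b@grid), ])^2))
  expect_lt(closure, 1)

  half <- circ[1:20, ]
  expect_error(fitBoundary(half, angles[1:20], df = 12), "90")
})

test_that("the breast pipeline is deterministic and accurate on a phantom", {
  ph <- torsoPhantom()
  lmR <- sideLandmarks(ph$landmarks, "R")
  res <- torsoResult()
  res2 <- breastBoundary(ph$cloud, lmR)
  expect_identical(res$boundary@grid, res2$boundary@grid)

  d <- polylineDistance(res$boundary@grid, ph$truth$boundaries$R)
  expect_lt(sqrt(mean(d^2)), 2)
  expect_equal(res$report$nTransects, 51L)
})
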