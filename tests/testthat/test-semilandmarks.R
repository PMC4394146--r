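test_that("exponential spacings match the quantile construction", {
  for (r in c(5, 20)) {
    tau <- exponentialSpacings(r)
    oracle <- qexp(seq_len(r) * 0.99 / r) / qexp(0.99)
    expect_equal(tau, oracle, tolerance = 1e-12)
    expect_true(all(diff(tau) > 0))
    expect_equal(tau[r], 1)
  }
  expect_error(exponentialSpacings(1), "at least 2")

  # on a straight transect, gaps are largest at the apex end and decrease
  # strictly toward the boundary
  sPos <- ancurve:::.apexSpacings(20, 100)
  gaps <- diff(c(0, sPos))
  expect_true(all(diff(gaps) < 0))
  expect_equal(sPos[20], 100)
})

test_that("the breast grid has 1021 corresponded points on the surface", {
  ph <- torsoPhantom()
  lmR <- sideLandmarks(ph$landmarks, "R")
  res <- torsoResult()
  g <- breastSemilandmarks(res, lmR, r = 20)
  expect_equal(nrow(coords(g)), 1021L)
  expect_equal(coords(g)[1, ], unname(landmark(lmR, "prom")))

  # last point of every transect lies on the fitted boundary curve
  last <- coords(g)[gridLabels(g)$index == 20, ]
  expect_lt(max(polylineDistance(last, res$boundary@grid)), 0.5)

  # same descriptor on a second run: identical labels and counts
  g2 <- breastSemilandmarks(res, lmR, r = 20)
  expect_identical(gridDescriptor(g), gridDescriptor(g2))
  expect_identical(gridLabels(g), gridLabels(g2))
  expect_identical(coords(g), coords(g2))
})

test_that("breast grids are equivariant under rigid motion", {
  ph <- torsoPhantom()
  lmR <- sideLandmarks(ph$landmarks, "R")
  res <- torsoResult()
  g <- breastSemilandmarks(res, lmR, r = 10)

  R <- rigidRot(0.3, c(0, 0, 1))
  shift <- c(12, -7, 30)
  cl2 <- SurfacePointCloud(sweep(coords(ph$cloud) %*% t(R), 2, shift, "+"),
                           normals = ph$cloud@normals %*% t(R))
  lm2 <- LandmarkSet({
    m <- sweep(coords(lmR) %*% t(R), 2, shift, "+")
    rownames(m) <- rownames(coords(lmR)); m
  })
  res2 <- breastBoundary(cl2, lm2)
  g2 <- breastSemilandmarks(res2, lm2, r = 10)
  ref <- sweep(coords(g) %*% t(R), 2, shift, "+")
  expect_lt(max(abs(coords(g2) - ref)), 0.01)
})

test_that("lip semi-landmarks follow the width ramp and correspond", {
  ph <- lipPhantom()
  res <- lipResult()
  g <- lipSemilandmarks(res$curves, ph$cloud, "upper", nBoundary = 30)
  counts <- gridDescriptor(g)$counts
  expect_equal(counts[1], 3L + 2L)           # 3 interior at the corners
  expect_equal(max(counts), 24L + 2L)        # 24 at the widest point
  expect_equal(counts, rev(counts))          # symmetric ramp
  expect_equal(nrow(coords(g)), sum(counts))
  # order: transect-major with index within transect
  expect_equal(gridLabels(g)$transect,
               rep(seq_along(counts), times = counts))

  g2 <- lipSemilandmarks(res$curves, ph$cloud, "upper", nBoundary = 30)
  expect_identical(coords(g), coords(g2))
})

test_that("triangulation has the documented face count and positive areas", {
  ph <- torsoPhantom()
  lmR <- sideLandmarks(ph$landmarks, "R")
  g <- breastSemilandmarks(torsoResult(), lmR, r = 20)
  f <- triangulateGrid(g)
  k <- 51; r <- 20
  expect_equal(nrow(f), k + 2 * k * (r - 1))
  P <- coords(g)
  areas <- vapply(seq_len(nrow(f)), function(i) {
    v <- f[i, ]
    sqrt(sum(ancurve:::.cross(P[v[2], ] - P[v[1], ],
                              P[v[3], ] - P[v[1], ])^2)) / 2
  }, 0)
  expect_true(all(areas > 0))

  # mirrored grid: same counts
  gm <- g
  gm@points <- cbind(-P[, 1], P[, 2], P[, 3])
  fm <- triangulateGrid(gm)
  expect_equal(dim(fm), dim(f))
})
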