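# "interior" below means the middle 60% of arc length: spline curvature is
# boundary-biased in the outer stretches, which the package masks when
# hunting maxima.
interiorIdx <- function(n) round(0.2 * n):round(0.8 * n)

test_that("planar curvature matches analytic values", {
  th <- seq(0, pi, length.out = 500)
  X <- cbind(30 * cos(th), 30 * sin(th))
  pc <- fitPrincipalCurve(X, df = 20, maxIter = 50)
  k <- abs(planarCurvature(pc)@kappa)
  ii <- interiorIdx(length(k))
  expect_lt(max(abs(k[ii] * 30 - 1)), 0.01)

  # straight line: zero curvature
  L <- cbind(seq(0, 100, length.out = 200), seq(0, 50, length.out = 200))
  kl <- planarCurvature(fitPrincipalCurve(L, df = 4))@kappa
  expect_lt(max(abs(kl), na.rm = TRUE), 1e-8)

  # parabola: kappa(0) = 2
  t <- seq(-1, 1, length.out = 600)
  pcp <- fitPrincipalCurve(cbind(t, t^2), df = 30, maxIter = 50)
  prof <- planarCurvature(pcp)
  i0 <- which.min(abs(pcp@grid[, 1]))
  expect_lt(abs(abs(prof@kappa[i0]) / 2 - 1), 0.01)
})

test_that("space curvature matches analytic values", {
  tt <- seq(0, 4 * pi, length.out = 800)
  helix <- cbind(10 * cos(tt), 10 * sin(tt), 5 * tt)
  pch <- fitPrincipalCurve(helix, df = 30, maxIter = 50)
  kh <- spaceCurvature(pch)@kappa
  ii <- interiorIdx(length(kh))
  expect_lt(max(abs(kh[ii] / 0.08 - 1)), 0.02)

  # planar circle arc embedded in 3D
  th <- seq(0, pi, length.out = 500)
  C3 <- cbind(25 * cos(th), 25 * sin(th), 0)
  kc <- spaceCurvature(fitPrincipalCurve(C3, df = 20, maxIter = 50))@kappa
  expect_lt(max(abs(kc[interiorIdx(length(kc))] * 25 - 1)), 0.01)

  # straight 3D segment
  L3 <- cbind(seq(0, 50, length.out = 100), seq(0, 30, length.out = 100),
              seq(0, -20, length.out = 100))
  kl <- spaceCurvature(fitPrincipalCurve(L3, df = 4))@kappa
  expect_lt(max(abs(kl), na.rm = TRUE), 1e-8)
})

test_that("curvature obeys the 1/length scale law", {
  th <- seq(0, pi, length.out = 400)
  for (cc in c(0.5, 2)) {
    X <- cc * cbind(20 * cos(th), 20 * sin(th))
    k <- abs(planarCurvature(fitPrincipalCurve(X, df = 15,
                                               maxIter = 50))@kappa)
    ii <- interiorIdx(length(k))
    expect_lt(max(abs(k[ii] * (20 * cc) - 1)), 0.02)
  }
})

test_that("planar curvature agrees with finite differences of the grid", {
  set.seed(8)
  th <- seq(0, pi, length.out = 400)
  X <- cbind(35 * cos(th), 35 * sin(th)) + matrix(rnorm(800, sd = 0.1),
                                                  ncol = 2)
  pc <- fitPrincipalCurve(X, df = 10, maxIter = 40)
  prof <- planarCurvature(pc)
  G <- pc@grid
  h <- diff(pc@sGrid[1:2])
  n <- nrow(G)
  d1 <- (G[3:n, ] - G[1:(n - 2), ]) / (2 * h)
  d2 <- (G[3:n, ] - 2 * G[2:(n - 1), ] + G[1:(n - 2), ]) / h^2
  kFD <- (d1[, 1] * d2[, 2] - d2[, 1] * d1[, 2]) /
    (d1[, 1]^2 + d1[, 2]^2)^1.5
  ii <- interiorIdx(n - 2)
  expect_lt(max(abs(kFD[ii] - prof@kappa[ii + 1])) /
              max(abs(prof@kappa[ii + 1])), 0.02)
})

test_that("local maxima extraction handles signs, plateaus and masks", {
  s <- seq(0, 100, length.out = 101)
  onebump <- exp(-(s - 40)^2 / 50)
  p <- new("CurvatureProfile", s = s, kappa = onebump)
  mx <- localCurvatureMaxima(p)
  expect_equal(nrow(mx), 1L)
  expect_equal(mx$s, 40)

  # a negative first maximum is excluded when positives are required
  two <- -0.3 + 0.2 * exp(-(s - 30)^2 / 50) + 0.8 * exp(-(s - 70)^2 / 50)
  neg <- new("CurvatureProfile", s = s, kappa = two)
  mxn <- localCurvatureMaxima(neg, requirePositive = TRUE)
  expect_true(all(mxn$kappa > 0))
  expect_true(all(abs(mxn$s - 70) < 5))
  mxb <- localCurvatureMaxima(neg, requirePositive = FALSE)
  expect_equal(nrow(mxb), 2L)
  expect_lt(mxb$kappa[1], 0)

  # plateau: first index reported
  k <- c(0, 1, 2, 2, 2, 1, 0)
  pp <- new("CurvatureProfile", s = as.numeric(1:7), kappa = k)
  mp <- localCurvatureMaxima(pp, endMask = 0)
  expect_equal(mp$s, 3)

  # end mask removes boundary maxima
  edge <- new("CurvatureProfile", s = s, kappa = exp(-(s - 1)^2 / 10))
  expect_equal(nrow(localCurvatureMaxima(edge, endMask = 0.05)), 0L)
})
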