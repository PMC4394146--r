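test_that("collinear points give the least-squares line in order", {
  t <- seq(0, 100, length.out = 60)
  X <- cbind(3 + 0.8 * t, -2 + 0.6 * t)
  pc <- fitPrincipalCurve(X, df = 3)
  # fitted points lie on the generating line
  d <- abs(0.6 * (pc@grid[, 1] - 3) - 0.8 * (pc@grid[, 2] + 2))
  expect_lt(max(d), 1e-6)
  expect_true(all(diff(order(pc@s)) == 1) || all(diff(order(-pc@s)) == 1))
})

test_that("a noisy semicircle is recovered", {
  set.seed(4)
  n <- 300
  th <- runif(n, 0, pi)
  X <- cbind(50 * cos(th), 50 * sin(th)) + matrix(rnorm(2 * n, sd = 0.5),
                                                  ncol = 2)
  pc <- fitPrincipalCurve(X, df = 8, maxIter = 60)
  expect_true(pc@converged)
  dev <- abs(sqrt(rowSums(pc@grid^2)) - 50)
  expect_lt(max(dev), 1.5)
  # self-consistency: re-smoothing against the converged arc lengths moves
  # the fitted coordinates by less than the convergence tolerance (scaled)
  refit <- vapply(1:2, function(j)
    psplineEval(fitPspline(pc@s, X[, j],
                           nbasis = length(pc@models[[j]]@beta),
                           df = 8, srange = range(pc@s)), pc@s),
    numeric(n))
  fitted <- evalCurve(pc, pc@s)
  expect_lt(max(abs(refit - fitted)) / 50, 1e-4)
})

test_that("projection matches a brute-force grid search", {
  set.seed(5)
  th <- seq(0, pi, length.out = 200)
  X <- cbind(40 * cos(th), 40 * sin(th)) + matrix(rnorm(400, sd = 0.3),
                                                  ncol = 2)
  pc <- fitPrincipalCurve(X, df = 8, maxIter = 40)
  sDense <- seq(0, pc@smax, length.out = 1e5)
  G <- evalCurve(pc, sDense)
  pts <- matrix(c(10, 50, -30, 20, 0, 0, 39, 1), ncol = 2, byrow = TRUE)
  pr <- projectToCurve(pc, pts)
  for (i in seq_len(nrow(pts))) {
    d2 <- colSums((t(G) - pts[i, ])^2)
    sBrute <- sDense[which.min(d2)]
    expect_lt(abs(pr$s[i] - sBrute), pc@smax / 1e3)
    expect_lt(abs(pr$distance[i] - sqrt(min(d2))), 1e-3)
  }
  # a point on the curve projects to itself
  onC <- evalCurve(pc, pc@smax * 0.37)[1, ]
  pOn <- projectToCurve(pc, onC)
  expect_lt(pOn$distance, 1e-6)
  expect_lt(abs(pOn$s - pc@smax * 0.37), pc@smax / 500)
})

test_that("equidistant ties resolve to the smallest arc length", {
  # a U-shaped curve: the centre point is equidistant from both arms
  t <- seq(-1, 1, length.out = 201)
  X <- cbind(t, t^2 * 20)
  pc <- fitPrincipalCurve(X, df = 10, maxIter = 40)
  mid <- c(0, 10)   # roughly equidistant from the two arms
  pr <- projectToCurve(pc, mid, refine = FALSE)
  sDense <- seq(0, pc@smax, length.out = 2e4)
  G <- evalCurve(pc, sDense)
  d2 <- colSums((t(G) - mid)^2)
  near <- sDense[d2 <= min(d2) * (1 + 1e-6)]
  expect_lte(pr$s, min(near) + pc@smax / 500)
})

test_that("extension is the end tangent line", {
  t <- seq(0, 10, length.out = 100)
  X <- cbind(2 * t + 1, -t + 3)
  pc <- fitPrincipalCurve(X, df = 3)
  ext <- extendCurve(pc, pc@smax + 5)
  f0 <- evalCurve(pc, pc@smax)[1, ]
  dirv <- (ext[1, ] - f0) / sqrt(sum((ext[1, ] - f0)^2))
  lineDir <- c(2, -1) / sqrt(5)
  expect_lt(min(sum((dirv - lineDir)^2), sum((dirv + lineDir)^2)), 1e-6)

  expect_equal(extendCurve(pc, pc@smax)[1, ], f0, tolerance = 1e-9)
  expect_error(extendCurve(pc, pc@smax / 2), "outside")

  # quadratic coordinate: extension equals the analytic tangent value
  sgrid <- seq(0, 10, length.out = 200)
  Q <- cbind(sgrid, 0.05 * sgrid^2)
  pcq <- fitPrincipalCurve(Q, df = 12, maxIter = 40)
  e <- extendCurve(pcq, pcq@smax + 2)
  f0 <- evalCurve(pcq, pcq@smax)[1, ]
  f1 <- evalCurve(pcq, pcq@smax, deriv = 1L)[1, ]
  expect_equal(e[1, ], f0 + 2 * f1, tolerance = 1e-8)
})

test_that("fitting is equivariant under rigid motions", {
  set.seed(6)
  th <- seq(0.2, pi - 0.2, length.out = 150)
  X3 <- cbind(30 * cos(th), 30 * sin(th), 2 * th) +
    matrix(rnorm(450, sd = 0.2), ncol = 3)
  pc <- fitPrincipalCurve(X3, df = 8, maxIter = 40, startNear = X3[1, ])
  R <- rigidRot(0.5, c(1, 1, 0))
  X3b <- sweep(X3 %*% t(R), 2, c(10, -5, 3), "+")
  pcb <- fitPrincipalCurve(X3b, df = 8, maxIter = 40, startNear = X3b[1, ])
  expect_equal(pcb@s, pc@s, tolerance = 1e-4)
  Gref <- sweep(evalCurve(pc, pc@sGrid) %*% t(R), 2, c(10, -5, 3), "+")
  expect_lt(max(abs(Gref - evalCurve(pcb, pcb@sGrid))), 1e-3)
})

test_that("projection distance does not increase across iterations", {
  set.seed(7)
  th <- runif(200, 0, pi)
  X <- cbind(40 * cos(th), 40 * sin(th)) + matrix(rnorm(400, sd = 0.5),
                                                  ncol = 2)
  d1 <- fitPrincipalCurve(X, df = 6, maxIter = 2)@distSq
  d2 <- fitPrincipalCurve(X, df = 6, maxIter = 60)@distSq
  expect_lte(d2, d1 * (1 + 1e-6))
})

test_that("preconditions are enforced", {
  expect_error(fitPrincipalCurve(cbind(1:5, 1:5), df = 6), "at least")
  expect_error(fitPrincipalCurve(cbind(1:50, 1:50), df = 1), "df")
})
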