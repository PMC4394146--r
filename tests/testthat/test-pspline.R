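test_that("penalty limits: straight line and interpolation", {
  set.seed(10)
  s <- seq(0, 10, length.out = 80)
  x <- sin(s) + rnorm(80, sd = 0.1)
  big <- fitPspline(s, x, nbasis = 20, lambda = 1e12)
  lf <- lm(x ~ s)
  expect_lt(max(abs(psplineEval(big, s) - fitted(lf))), 1e-6)

  s2 <- (0:14) * (10 / 15) + runif(15, 0.05, 0.6)   # distinct, well spaced
  x2 <- rnorm(15)
  interp <- fitPspline(s2, x2, nbasis = 18, lambda = 0)
  expect_lt(max(abs(psplineEval(interp, s2) - x2)), 1e-8)
})

test_that("df calibration hits the requested hat-matrix trace", {
  set.seed(11)
  s <- seq(0, 50, length.out = 200)
  x <- cos(s / 5) + rnorm(200, sd = 0.05)
  f <- fitPspline(s, x, nbasis = 30, df = 25)
  expect_lt(abs(f@df - 25), 0.05)
  f2 <- fitPspline(s, x, nbasis = 20, df = 6)
  expect_lt(abs(f2@df - 6), 0.05)
})

test_that("equality constraints reproduce a quadratic-programming oracle", {
  # oracle: minimise ||x - B b||^2 + lambda |D2 b|^2 s.t. A b = c via the
  # KKT system [2M  A'; A  0] [b; mu] = [2 B'x; c]
  set.seed(12)
  for (rep in 1:20) {
    n <- 40; nb <- 12
    s <- sort(runif(n, 0, 1))
    x <- rnorm(n)
    f <- fitPspline(s, x, nbasis = nb, df = runif(1, 4, 9),
                    srange = c(0, 1))
    at <- sort(runif(2, 0.1, 0.9))
    cv <- rnorm(2)
    fc <- constrainThroughPoints(f, at, cv, s, x)
    expect_lt(max(abs(psplineEval(fc, at) - cv)), 1e-8)

    B <- ancurve:::.psplineBasis(s, f@knots, f@degree)
    D2 <- ancurve:::.diffOp(nb, 2L)
    A <- ancurve:::.psplineBasis(at, f@knots, f@degree)
    M <- crossprod(B) + f@lambda * crossprod(D2)
    KKT <- rbind(cbind(2 * M, t(A)), cbind(A, matrix(0, 2, 2)))
    sol <- solve(KKT, c(2 * crossprod(B, x), cv))
    expect_lt(max(abs(fc@beta - sol[1:nb])), 1e-8)
  }
})

test_that("constraining is a no-op when already satisfied, and linear", {
  set.seed(13)
  s <- seq(0, 1, length.out = 50)
  x <- s^2 + rnorm(50, sd = 0.05)
  f <- fitPspline(s, x, nbasis = 12, df = 6)
  at <- c(0.3, 0.8)
  already <- drop(ancurve:::.psplineBasis(at, f@knots, f@degree) %*% f@beta)
  f0 <- constrainThroughPoints(f, at, already, s, x)
  expect_equal(f0@beta, f@beta, tolerance = 1e-10)

  # joint rescaling of x and c rescales the solution (linearity)
  cv <- c(0.2, 0.9)
  f1 <- constrainThroughPoints(f, at, cv, s, x)
  f3 <- fitPspline(s, 3 * x, nbasis = 12, lambda = f@lambda)
  f3c <- constrainThroughPoints(f3, at, 3 * cv, s, 3 * x)
  expect_equal(f3c@beta, 3 * f1@beta, tolerance = 1e-8)
})

test_that("shape penalties are inert on compliant data and active on dips", {
  set.seed(14)
  s <- seq(0, 1, length.out = 120)
  # upper-lip-shaped: rises then falls; compliant with upperLipShape
  x <- sin(pi * s) + rnorm(120, sd = 0.01)
  fc <- fitShapeConstrained(s, x, nbasis = 20, df = 10,
                            shapes = upperLipShape())
  expect_true(fc@converged)
  plain <- fitPspline(s, x, nbasis = 20, df = 10)
  expect_lt(max(abs(psplineEval(fc, s) - psplineEval(plain, s))), 0.05)
  m <- ancurve:::.shapeMasks(fc@beta, fc@knots, fc@degree, fc@srange,
                             upperLipShape())
  expect_true(all(m$v1 == 0))

  # an artificial dip in the first 40%: monotone penalty suppresses it
  xd <- x - 0.6 * exp(-(s - 0.2)^2 / 0.002)
  fd <- fitShapeConstrained(s, xd, nbasis = 25, df = 18,
                            shapes = upperLipShape())
  grid <- seq(0.02, 0.38, length.out = 80)
  d1 <- diff(psplineEval(fd, grid))
  expect_gt(min(d1), -1e-3 * diff(range(xd)))
  # without the penalty the dip survives
  fp <- fitPspline(s, xd, nbasis = 25, df = 18)
  expect_lt(min(diff(psplineEval(fp, grid))), -1e-2 * diff(range(xd)))
})

test_that("the mask iteration descends the penalised objective", {
  set.seed(15)
  s <- seq(0, 1, length.out = 100)
  x <- sin(pi * s) - 0.4 * exp(-(s - 0.25)^2 / 0.004) + rnorm(100, 0.01)
  f <- fitShapeConstrained(s, x, nbasis = 22, df = 15,
                           shapes = upperLipShape())
  B <- ancurve:::.psplineBasis(s, f@knots, f@degree)
  m <- ancurve:::.shapeMasks(f@beta, f@knots, f@degree, f@srange,
                             upperLipShape())
  # with the converged masks fixed, the returned beta minimises S(beta):
  # any perturbation increases the objective
  S0 <- ancurve:::.shapeObjective(f@beta, B, x, f@lambda, f@kappa,
                                  m$v1, m$v2)
  for (i in 1:5) {
    pert <- f@beta + rnorm(length(f@beta), sd = 0.01)
    expect_gte(ancurve:::.shapeObjective(pert, B, x, f@lambda, f@kappa,
                                         m$v1, m$v2), S0)
  }
})

test_that("the smoother matches an independent eigendecomposition oracle", {
  set.seed(16)
  s <- seq(0, 2, length.out = 150)
  x <- exp(-s) * sin(4 * s) + rnorm(150, sd = 0.02)
  f <- fitPspline(s, x, nbasis = 24, df = 12)
  B <- ancurve:::.psplineBasis(s, f@knots, f@degree)
  P <- crossprod(ancurve:::.diffOp(24L, 2L))
  # oracle: solve via eigendecomposition of M rather than QR
  M <- crossprod(B) + f@lambda * P
  ev <- eigen(M, symmetric = TRUE)
  bOracle <- ev$vectors %*% ((t(ev$vectors) %*% crossprod(B, x)) /
                             ev$values)
  expect_lt(max(abs(B %*% bOracle - psplineEval(f, s))), 1e-6)
})
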