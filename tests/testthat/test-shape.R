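# a small corresponded configuration for shape tests: a bumpy grid
baseConfig <- function(p = 60) {
  set.seed(30)
  u <- runif(p, -1, 1); v <- runif(p, -1, 1)
  cbind(u, v, 0.3 * u^2 - 0.2 * v^2)
}

test_that("superimposition removes rigid motion exactly", {
  X <- baseConfig()
  expect_equal(procrustesDistance(X, X), 0, tolerance = 1e-12)
  Y <- rigid(X, 0.8, c(1, 2, 0), c(5, 5, -2))
  expect_lt(procrustesDistance(X, Y), 1e-9)

  s <- superimpose(ShapeSample(list(X, Y)))
  expect_lt(max(abs(configuration(s, 1) - configuration(s, 2))), 1e-9)

  degenerate <- matrix(1, 20, 3)
  expect_error(superimpose(ShapeSample(list(degenerate, X[1:20, ]))),
               "degenerate")
})

test_that("the aligned mean is a fixed point and sizes are preserved", {
  set.seed(31)
  X <- baseConfig()
  confs <- lapply(1:6, function(i)
    rigid(X + matrix(rnorm(length(X), sd = 0.02), nrow(X)),
          runif(1, 0, 1), rnorm(3), rnorm(3, sd = 5)))
  samp <- ShapeSample(confs)
  sizes0 <- centroidSizes(samp)
  al <- superimpose(samp)
  expect_equal(centroidSizes(al), sizes0, tolerance = 1e-9)

  ref <- apply(al@configs, c(1, 2), mean)
  for (i in 1:6) {
    Ropt <- ancurve:::.kabsch(al@configs[, , i], ref)
    expect_lt(max(abs(Ropt - diag(3))), 1e-4)
  }
})

test_that("the pairwise rotation agrees with vegan's procrustes", {
  skip_if_not_installed("vegan")
  set.seed(32)
  X <- baseConfig(40)
  Y <- rigid(X + matrix(rnorm(120, sd = 0.05), 40), 0.5, c(0, 1, 1))
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  ours <- Yc %*% ancurve:::.kabsch(Yc, Xc)
  vg <- vegan::procrustes(Xc, Yc, scale = FALSE)
  expect_lt(max(abs(ours - vg$Yrot)), 1e-8)
})

test_that("shape PCA conserves variance and recovers a planted mode", {
  set.seed(33)
  X <- baseConfig()
  defo <- matrix(rnorm(length(X)), nrow(X))
  defo <- defo / sqrt(sum(defo^2))
  alpha <- rnorm(20, sd = 2)
  confs <- lapply(alpha, function(a)
    X + a * defo + matrix(rnorm(length(X), sd = 0.01), nrow(X)))
  al <- superimpose(ShapeSample(confs), removeScale = FALSE)
  # skip alignment effects: these configurations are already registered
  pca <- shapePCA(ShapeSample(confs))
  V <- t(apply(ShapeSample(confs)@configs, 3, as.vector))
  expect_lt(abs(sum(pca@sdev^2) - sum(diag(var(V)))), 1e-8)
  expect_gt(abs(cor(pca@loadings[, 1], as.vector(defo))), 0.99)

  # reconstruction identities
  expect_equal(shapeAtScore(pca, 1, 0), pca@mean)
  plus <- shapeAtScore(pca, 1, 2); minus <- shapeAtScore(pca, 1, -2)
  expect_equal((plus + minus) / 2, pca@mean, tolerance = 1e-10)
  sc <- sum((as.vector(plus) - as.vector(pca@mean)) * pca@loadings[, 1])
  expect_equal(sc, 2 * pca@sdev[1], tolerance = 1e-8)

  # specimen order only flips signs
  pca2 <- shapePCA(ShapeSample(rev(confs)))
  c1 <- abs(cor(pca@loadings[, 1], pca2@loadings[, 1]))
  expect_gt(c1, 0.9999)
})

test_that("paired score comparisons behave", {
  set.seed(34)
  X <- baseConfig()
  confs <- lapply(1:8, function(i)
    X + matrix(rnorm(length(X), sd = 0.05), nrow(X)))
  confs <- c(confs, confs)     # identical pairs
  pca <- shapePCA(ShapeSample(confs))
  pairs <- cbind(1:8, 9:16)
  out <- pairedScoreTest(pca, pairs)
  expect_equal(out$meanDiff, c(0, 0))
  expect_equal(out$t, c(0, 0))

  # antisymmetry under swapping pair roles
  confs2 <- lapply(1:16, function(i)
    X + matrix(rnorm(length(X), sd = 0.05), nrow(X)))
  pca2 <- shapePCA(ShapeSample(confs2))
  a <- pairedScoreTest(pca2, pairs)
  b <- pairedScoreTest(pca2, pairs[, 2:1])
  expect_equal(a$t, -b$t, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)

  expect_error(pairedScoreTest(pca2, pairs[1:2, ]), "at least 3")
})

test_that("paired test power matches the analytic power of the t-test", {
  set.seed(35)
  n <- 15; delta <- 1; sdd <- 1
  anaPower <- power.t.test(n = n, delta = delta, sd = sdd,
                           type = "one.sample")$power
  mkModel <- function(d) {
    sc <- cbind(c(d, 0), rnorm(n + 1))
    new("ShapePCAModel", mean = matrix(0, 2, 3),
        loadings = diag(6)[, 1:2], scores = sc, sdev = c(2, 1))
  }
  hits <- mean(replicate(400, {
    d <- rnorm(n, mean = delta, sd = sdd)
    out <- pairedScoreTest(mkModel(d), cbind(1:n, rep(n + 1, n)),
                           components = 1)
    out$p < 0.05
  }))
  expect_lt(abs(hits - anaPower), 0.1)
})
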