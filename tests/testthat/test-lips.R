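test_that("vertical strips follow the mouth frame", {
  ph <- lipPhantom()
  vs <- verticalStrips(ph$cloud)
  expect_length(vs$strips, 50L)
  # the elongated patch puts n1 within 5 degrees of the true mouth axis
  expect_lt(acos(min(abs(sum(vs$axes[, 1] * c(1, 0, 0))), 1)),
            5 * pi / 180)
  # strips are pairwise disjoint when offsets are > 2 delta apart
  i1 <- vs$strips[[10]]; i2 <- vs$strips[[13]]
  expect_gt(abs(vs$offsets[13] - vs$offsets[10]), 2 * 1.2)
  common <- intersect(
    apply(round(coords(i1), 6), 1, paste, collapse = ","),
    apply(round(coords(i2), 6), 1, paste, collapse = ","))
  expect_length(common, 0L)
})

test_that("midline and ridge candidates are found where they exist", {
  ph <- lipPhantom()
  vs <- verticalStrips(ph$cloud)
  mid <- which.min(abs(vs$offsets))
  r <- detectLipPoints(vs$strips[[mid]])
  expect_false(is.null(r$midline))
  expect_lt(polylineDistance(rbind(r$midline$point), ph$truth$midline), 1)
  expect_gt(nrow(r$upper), 0)
  expect_gt(nrow(r$lower), 0)
  iu <- which.max(r$upper$kappa); il <- which.max(r$lower$kappa)
  expect_lt(polylineDistance(as.matrix(r$upper[iu, c("x", "y", "z")]),
                             ph$truth$upper), 1.5)
  expect_lt(polylineDistance(as.matrix(r$lower[il, c("x", "y", "z")]),
                             ph$truth$lower), 1.5)

  # lateral strip: no midline, hence no candidates
  lat <- which.max(vs$offsets)
  rl <- detectLipPoints(vs$strips[[lat]])
  expect_null(rl$midline)
  expect_equal(nrow(rl$upper), 0L)
  expect_equal(nrow(rl$lower), 0L)
})

test_that("multiple candidates resolve toward the preliminary curve", {
  # synthetic per-strip results: true ridge along y = 0 at z = 10, with a
  # planted spurious candidate 8 mm away on strip 5
  mkres <- function() {
    lapply(1:12, function(i) {
      x <- i * 2
      cand <- data.frame(s = 10, kappa = 1, x = x, y = 0, z = 10)
      list(upper = cand, lower = cand[0, ], curve = NULL, strip = NULL)
    })
  }
  res <- mkres()
  out <- resolveMultipleCandidates(res, "upper")
  expect_identical(out, lapply(res, `[[`, "upper"))

  # build a genuine geometry for the multi-candidate case
  ph <- lipPhantom()
  vs <- verticalStrips(ph$cloud)
  results <- lapply(14:36, function(i) {
    r <- detectLipPoints(vs$strips[[i]])
    r$strip <- vs$strips[[i]]
    r
  })
  # plant a spurious far candidate on one strip that has a single true one
  k <- which(vapply(results, function(r) nrow(r$upper) == 1, TRUE))[1]
  expect_false(is.na(k))
  true1 <- results[[k]]$upper
  spur <- true1
  spur$s <- spur$s + 8
  fp <- evalCurve(results[[k]]$curve, spur$s)
  p3 <- ancurve:::.stripTo3D(results[[k]]$strip, fp[, 1], fp[, 2])
  spur$x <- p3[1]; spur$y <- p3[2]; spur$z <- p3[3]
  results[[k]]$upper <- rbind(true1, spur)
  out2 <- resolveMultipleCandidates(results, "upper")
  expect_equal(nrow(out2[[k]]), 1L)
  expect_equal(out2[[k]]$s, true1$s)

  # exact tie: the smaller arc length wins
  cd <- data.frame(s = c(4, 6), kappa = c(1, 1), x = 0, y = 0, z = 0)
  dist <- abs(cd$s - 5)
  keep <- which(dist == min(dist))
  expect_equal(cd$s[keep[which.min(cd$s[keep])]], 4)
})

test_that("corners are recovered from midline curvature", {
  ph <- lipPhantom()
  res <- lipResult()
  ci <- res$corners
  eL <- sqrt(sum((ci$corners["L", ] - ph$truth$corners["L", ])^2))
  eR <- sqrt(sum((ci$corners["R", ] - ph$truth$corners["R", ])^2))
  expect_lt(eL, 1.5)
  expect_lt(eR, 1.5)
  # symmetric phantom: corner arc lengths symmetric about the midpoint
  smax <- ci$curve@smax
  expect_lt(abs((ci$sL + ci$sR) / 2 - smax / 2) / smax, 0.05)
  expect_error(findCorners(matrix(rnorm(9), 3, 3)), "at least 10")
})

test_that("fitted boundary curves pass through the corners and fit truth", {
  ph <- lipPhantom()
  res <- lipResult()
  crv <- res$curves
  for (w in c("upper", "lower", "midline")) {
    ends <- evalLipCurve(crv, w, c(crv@sL, crv@sR))
    expect_lt(sqrt(sum((ends[1, ] - crv@corners["L", ])^2)), 1e-6)
    expect_lt(sqrt(sum((ends[2, ] - crv@corners["R", ])^2)), 1e-6)
  }
  expect_lt(lipCurveAgreement(crv, "midline", ph$truth$midline)["overall"],
            1.5)
})

test_that("candidates beyond the corners are discarded in the fits", {
  res <- lipResult()
  crv <- res$curves
  # every evaluation stays within the corner span by construction
  s <- seq(crv@sL, crv@sR, length.out = 51)
  expect_true(all(s >= crv@sL & s <= crv@sR))
  # report bookkeeping
  expect_gte(res$report$nMidline, 10L)
})
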