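# Statistical shape analysis of corresponded semi-landmark grids:
# generalized Procrustes superimposition, principal components of the
# aligned configurations, score-to-shape reconstruction and paired/group
# score comparisons.

#' Build a shape sample from configurations
#'
#' @param configs list of p x 3 matrices (equal p), or a p x 3 x n array.
#' @param ids optional specimen ids.
#' @param meta optional per-specimen data.frame.
#' @return a \linkS4class{ShapeSample}.
#' @export
ShapeSample <- function(configs, ids = NULL, meta = NULL) {
  if (is.list(configs)) {
    p <- nrow(configs[[1L]])
    if (!all(vapply(configs, nrow, 0L) == p))
      stop("all configurations must have the same number of points")
    arr <- array(NA_real_, c(p, 3L, length(configs)))
    for (i in seq_along(configs)) arr[, , i] <- as.matrix(configs[[i]])
    configs <- arr
  }
  n <- dim(configs)[3]
  if (is.null(ids)) ids <- sprintf("spec%02d", seq_len(n))
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  new("ShapeSample", configs = configs, ids = as.character(ids), meta = meta)
}

#' Number of specimens in a shape sample
#' @param x a \linkS4class{ShapeSample}.
#' @export
setMethod("length", "ShapeSample", function(x) dim(x@configs)[3])

#' Extract one configuration
#' @param x a \linkS4class{ShapeSample}.
#' @param i specimen index.
#' @export
configuration <- function(x, i) x@configs[, , i]

#' Centroid sizes of all configurations
#' @param x a \linkS4class{ShapeSample}.
#' @return numeric(n) centroid sizes (root summed squared deviations from
#'   the centroid).
#' @export
centroidSizes <- function(x) {
  apply(x@configs, 3, function(M)
    sqrt(sum(scale(M, scale = FALSE)^2)))
}

# optimal rotation of X onto Y (both centred): Kabsch, proper rotation
.kabsch <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalized Procrustes superimposition
#'
#' Iteratively translates (and optionally scales) and rotates all
#' configurations onto their evolving mean until the mean stabilises.
#' Scale is retained by default: size is then free to appear in the first
#' principal component of shape variation (a full similarity
#' superimposition is obtained with \code{removeScale = TRUE}).
#'
#' @param sample a \linkS4class{ShapeSample} (n >= 2).
#' @param removeScale scale configurations to unit centroid size first.
#' @param maxIter,tol iteration controls.
#' @return the aligned \linkS4class{ShapeSample}.
#' @export
superimpose <- function(sample, removeScale = FALSE, maxIter = 100L,
                        tol = 1e-10) {
  arr <- sample@configs
  n <- dim(arr)[3]
  if (n < 2L) stop("need at least 2 configurations")
  for (i in seq_len(n)) {
    M <- scale(arr[, , i], scale = FALSE)
    cs <- sqrt(sum(M^2))
    if (cs < 1e-12) stop("configuration ", i, " is degenerate (all points ",
                         "coincident)")
    if (removeScale) M <- M / cs
    arr[, , i] <- M
  }
  ref <- arr[, , 1L]
  for (it in seq_len(maxIter)) {
    for (i in seq_len(n))
      arr[, , i] <- arr[, , i] %*% .kabsch(arr[, , i], ref)
    newRef <- apply(arr, c(1, 2), mean)
    if (sqrt(sum((newRef - ref)^2)) < tol * max(1, sqrt(sum(ref^2)))) {
      ref <- newRef
      break
    }
    ref <- newRef
  }
  out <- sample
  out@configs <- arr
  out
}

#' Full Procrustes distance between two configurations
#'
#' Root-mean-square distance after optimal translation and rotation
#' (and optional scaling).
#'
#' @param X,Y p x 3 configurations.
#' @param removeScale also optimise scale.
#' @return non-negative distance.
#' @export
procrustesDistance <- function(X, Y, removeScale = FALSE) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  if (removeScale) {
    X <- X / sqrt(sum(X^2))
    Y <- Y / sqrt(sum(Y^2))
  }
  X <- X %*% .kabsch(X, Y)
  sqrt(sum((X - Y)^2))
}

#' Principal components of aligned shapes
#'
#' Covariance PCA of the vectorised aligned configurations (raw mm
#' coordinates, so with scale retained the first component is free to
#' express size).  Loading signs are fixed so each component's largest-
#' magnitude element is positive.
#'
#' @param sample an aligned \linkS4class{ShapeSample} (n >= 3).
#' @return a \linkS4class{ShapePCAModel}.
#' @export
shapePCA <- function(sample) {
  n <- length(sample)
  if (n < 3L) stop("need at least 3 specimens")
  X <- t(apply(sample@configs, 3, as.vector))   # n x 3p
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  m <- sum(pc$sdev > 1e-12)
  load <- pc$rotation[, seq_len(m), drop = FALSE]
  sc <- pc$x[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      sc[, j] <- -sc[, j]
    }
  }
  p <- dim(sample@configs)[1]
  new("ShapePCAModel",
      mean = matrix(colMeans(X), p, 3L),
      loadings = load, scores = sc, sdev = pc$sdev[seq_len(m)])
}

#' Shape at a principal component score
#'
#' Reconstructs mean + multiple * sd * loading as a configuration; the
#' conventional displays use multiples of -2 and +2 (2 standard deviations
#' either side of the mean shape).
#'
#' @param model a \linkS4class{ShapePCAModel}.
#' @param component component index.
#' @param multiple score in units of the component's sd (default 2).
#' @return p x 3 configuration.
#' @export
shapeAtScore <- function(model, component = 1L, multiple = 2) {
  if (component > ncol(model@loadings)) stop("component out of range")
  v <- as.vector(model@mean) +
    multiple * model@sdev[component] * model@loadings[, component]
  matrix(v, nrow(model@mean), 3L)
}

#' Paired comparison of principal component scores
#'
#' Paired t-tests of within-pair score differences per component (e.g.
#' reconstructed vs unreconstructed breasts from the same woman).
#'
#' @param model a \linkS4class{ShapePCAModel}.
#' @param pairs 2-column matrix of specimen indices (first minus second).
#' @param components components to test (default first 2).
#' @param conf confidence level (default 0.95, i.e. assessment at the 5\%
#'   level).
#' @return data.frame with mean difference, confidence limits, t and p per
#'   component.
#' @export
pairedScoreTest <- function(model, pairs, components = 1:2, conf = 0.95) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3L) stop("need at least 3 pairs")
  out <- lapply(components, function(cc) {
    d <- model@scores[pairs[, 1], cc] - model@scores[pairs[, 2], cc]
    eps <- 1e-9 * (stats::sd(model@scores[, cc]) + 1e-300)
    if (stats::sd(d) < eps && abs(mean(d)) < eps) {
      # numerically identical pairs: report exact zeros
      d <- rep(0, length(d))
    }
    if (stats::sd(d) < 1e-300) {
      data.frame(component = cc, meanDiff = mean(d), lo = mean(d),
                 hi = mean(d), t = 0, p = 1)
    } else {
      tt <- t.test(d, conf.level = conf)
      data.frame(component = cc, meanDiff = mean(d),
                 lo = tt$conf.int[1], hi = tt$conf.int[2],
                 t = unname(tt$statistic), p = tt$p.value)
    }
  })
  do.call(rbind, out)
}

#' Two-group comparison of principal component scores
#'
#' Welch t-tests of mean scores between two groups (e.g. male vs female
#' lip shapes).
#'
#' @param model a \linkS4class{ShapePCAModel}.
#' @param group logical or factor of length n (two levels).
#' @param components components to test (default first 2).
#' @return data.frame with mean difference, t and p per component.
#' @export
groupScoreTest <- function(model, group, components = 1:2) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  out <- lapply(components, function(cc) {
    tt <- t.test(model@scores[, cc] ~ g)
    data.frame(component = cc,
               meanDiff = diff(rev(tt$estimate)),
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Write PCA scores (and loadings) as CSV
#'
#' @param model a \linkS4class{ShapePCAModel}.
#' @param path output path for scores; loadings go to a sibling file with
#'   suffix "_loadings".
#' @export
writeScoresCSV <- function(model, path) {
  utils::write.csv(as.data.frame(model@scores), path, row.names = FALSE)
  lp <- sub("(\\.[^.]+)$", "_loadings\\1", path)
  utils::write.csv(as.data.frame(model@loadings), lp, row.names = FALSE)
  invisible(path)
}
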