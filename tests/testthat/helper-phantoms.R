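# Shared fixtures, built lazily and cached for the whole test run.  The
# torso and lip phantoms are generated at their default (study-scale)
# conditions once; the expensive pipeline results are cached alongside.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

torsoPhantom <- function() cached("torso", makeTorsoPhantom(torsoSpec(seed = 42L)))

torsoResult <- function() cached("torsoRes", {
  ph <- torsoPhantom()
  breastBoundary(ph$cloud, sideLandmarks(ph$landmarks, "R"))
})

lipPhantom <- function() cached("lip", makeLipPhantom(lipSpec(seed = 42L)))

lipResult <- function() cached("lipRes", lipBoundaries(lipPhantom()$cloud))

# a light synthetic hemisphere-on-plane cloud for unit tests of the
# candidate mechanism (dense, idealized; not the study-scale phantom)
capOnPlane <- function(n = 8000, r = 40, rb = 30, seed = 1) {
  set.seed(seed)
  u <- runif(n, -80, 80); v <- runif(n, -80, 80)
  rho <- sqrt(u^2 + v^2)
  h <- ifelse(rho <= rb, sqrt(pmax(r^2 - rho^2, 0)) - sqrt(r^2 - rb^2), 0)
  SurfacePointCloud(cbind(u, v, h))
}

# rigid motion helper
rigid <- function(P, angle = 0.4, axis = c(0, 0, 1), shift = c(4, -2, 7)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(P %*% t(R), 2, shift, "+")
}

rigidRot <- function(angle = 0.4, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
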