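# Run configuration and the top-level pipeline driver used by the command
# line wrapper (inst/cli/ancurve.R).  Every tunable constant is surfaced in
# the configuration — adjusting the exclusion constants is the intended
# manual-intervention mechanism when an estimate needs correction.

#' Default run configuration
#'
#' All tunables with their defaults: slab tolerances (1 mm torso, 1.2 mm
#' lips), the 12 mm neighbourhood radius, transect counts (51 radial, 50
#' vertical), smoothing degrees of freedom (6 transect, 8 lip strip, 12
#' boundary, 25 lip boundary), exclusion constants (0.7 and 10 mm), the
#' change-point threshold 5, the shape-penalty factor 100, semi-landmark
#' counts (r = 20, 50 per lip boundary) and the random seed.
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
  list(torso_delta = 1, lip_delta = 1.2, radius = 12,
       n_transects = 51L, n_strips = 50L,
       transect_df = 6, strip_df = 8, boundary_df = 12, lip_boundary_df = 25,
       proportion = 0.7, tolerance = 10,
       threshold = 5, kappa_factor = 100, length_factor = 1.5,
       r = 20L, n_boundary = 50L, seed = 1L)
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults.  The
#' parsed configuration round-trips through \code{yaml::as.yaml}.
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return named list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, user)
}

#' Run a named pipeline end to end
#'
#' Tasks: \code{"phantom"} (generate a torso or lip phantom and write it
#' out), \code{"breast"} (boundary + semi-landmarks from a cloud and
#' landmark file) and \code{"lips"} (boundary curves + semi-landmarks from
#' a mouth-region cloud).  Outputs, a JSON run report and return values
#' are written under \code{outDir}.
#'
#' @param task one of "phantom", "breast", "lips".
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @param cloud a \linkS4class{SurfacePointCloud} or path to a PLY/OBJ file.
#' @param landmarks a \linkS4class{LandmarkSet} or path to a landmark CSV.
#' @param outDir output directory (created if needed); NULL for no files.
#' @param kind phantom kind ("torso" or "lip") for the phantom task.
#' @param side breast side ("R" or "L") when the landmark set carries
#'   side-suffixed names.
#' @return invisible list of computed artifacts plus the \code{report}.
#' @export
runPipeline <- function(task = c("breast", "lips", "phantom"),
                        config = defaultConfig(), cloud = NULL,
                        landmarks = NULL, outDir = NULL, kind = "torso",
                        side = "R") {
  task <- match.arg(task)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(name, fn) if (!is.null(outDir)) fn(file.path(outDir, name))
  if (is.character(cloud)) {
    cloud <- if (grepl("\\.obj$", cloud, ignore.case = TRUE)) readOBJ(cloud)
             else readPLY(cloud)
  }
  if (is.character(landmarks)) {
    if (!file.exists(landmarks)) stop("landmark file not found: ", landmarks)
    landmarks <- readLandmarksCSV(landmarks)
  }
  if (!is.null(landmarks) && !"prom" %in% landmarkNames(landmarks) &&
      paste0("prom_", side) %in% landmarkNames(landmarks))
    landmarks <- sideLandmarks(landmarks, side)
  out <- switch(task,
    phantom = {
      ph <- if (kind == "torso")
        makeTorsoPhantom(torsoSpec(seed = config$seed))
      else makeLipPhantom(lipSpec(seed = config$seed))
      emit("cloud.ply", function(p) writePLY(ph$cloud, p))
      emit("landmarks.csv", function(p) writeLandmarksCSV(ph$landmarks, p))
      tc <- if (kind == "torso") ph$truth$boundaries
            else Filter(Negate(is.null),
                        ph$truth[c("upper", "midline", "lower")])
      emit("truth_curves.csv", function(p) writeCurvesCSV(tc, p))
      c(ph, list(report = list(task = task, kind = kind,
                               nPoints = length(ph$cloud))))
    },
    breast = {
      if (is.null(cloud) || is.null(landmarks))
        stop("breast task needs a cloud and landmarks")
      res <- breastBoundary(cloud, landmarks,
                            nTransects = config$n_transects,
                            delta = config$torso_delta,
                            df = config$transect_df,
                            boundaryDf = config$boundary_df,
                            radius = config$radius,
                            proportion = config$proportion,
                            tolerance = config$tolerance,
                            lengthFactor = config$length_factor)
      grid <- breastSemilandmarks(res, landmarks, r = config$r,
                                  df = config$transect_df)
      emit("boundary.csv", function(p) {
        b <- res$boundary
        utils::write.csv(data.frame(
          transect_index = seq_along(b@angles), angle = b@angles,
          x = b@points[, 1], y = b@points[, 2], z = b@points[, 3],
          interpolated = b@interpolated), p, row.names = FALSE)
      })
      emit("semilandmarks.csv", function(p) writeGridCSV(grid, p))
      list(boundary = res, grid = grid,
           report = c(res$report, list(task = task)))
    },
    lips = {
      if (is.null(cloud)) stop("lips task needs a cloud")
      res <- lipBoundaries(cloud, k = config$n_strips,
                           delta = config$lip_delta,
                           stripDf = config$strip_df,
                           threshold = config$threshold,
                           boundaryDf = config$lip_boundary_df,
                           kappaFactor = config$kappa_factor)
      for (nm in c("upper", "midline", "lower")) {
        local({
          w <- nm
          emit(paste0(w, "_curve.csv"), function(p) {
            s <- seq(res$curves@sL, res$curves@sR, length.out = 200L)
            M <- evalLipCurve(res$curves, w, s)
            utils::write.csv(data.frame(s = s, x = M[, 1], y = M[, 2],
                                        z = M[, 3]), p, row.names = FALSE)
          })
        })
      }
      emit("corners.json", function(p)
        jsonlite::write_json(list(
          L = unname(res$curves@corners["L", ]),
          R = unname(res$curves@corners["R", ]),
          sL = res$curves@sL, sR = res$curves@sR), p,
          digits = NA, auto_unbox = TRUE))
      emit("strip_diagnostics.csv", function(p)
        utils::write.csv(data.frame(
          strip = seq_along(res$results),
          statistic = vapply(res$results, `[[`, 0, "statistic"),
          midline = vapply(res$results,
                           function(r) !is.null(r$midline), TRUE),
          n_upper = vapply(res$results, function(r) nrow(r$upper), 0L),
          n_lower = vapply(res$results, function(r) nrow(r$lower), 0L)),
          p, row.names = FALSE))
      list(lips = res, report = c(res$report, list(task = task)))
    })
  if (!is.null(outDir))
    jsonlite::write_json(out$report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out)
}
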