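# Point-cloud and landmark I/O.  PLY (ASCII and binary little-endian
# vertices) and OBJ vertices are read and written directly — only the
# vertex data are used, faces and other elements are skipped.  Landmarks
# and curves travel as CSV (name/curve_id, x_mm, y_mm, z_mm) or JSON.

.plyTypeSize <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                  float = 4L, float32 = 4L, double = 8L, float64 = 8L)

#' Read a PLY point cloud
#'
#' Supports ASCII and binary_little_endian PLY; reads the vertex element's
#' x/y/z (and nx/ny/nz when present), skipping other properties and
#' elements.
#'
#' @param path PLY file path.
#' @return a \linkS4class{SurfacePointCloud}.
#' @export
readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    header <- c(header, ln)
    if (identical(ln, "end_header")) break
    if (length(header) > 200L) stop("PLY header not terminated")
  }
  fmt <- grep("^format ", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format: ", fmt)
  # parse elements and their properties
  elems <- list(); cur <- NULL
  for (ln in header) {
    w <- strsplit(trimws(ln), "\\s+")[[1]]
    if (w[1] == "element") {
      cur <- w[2]
      elems[[cur]] <- list(n = as.integer(w[3]), props = character(),
                           types = character())
    } else if (w[1] == "property" && !is.null(cur)) {
      if (w[2] == "list") {
        elems[[cur]]$props <- c(elems[[cur]]$props, paste0("list:", w[5]))
        elems[[cur]]$types <- c(elems[[cur]]$types,
                                paste(w[3], w[4], sep = ":"))
      } else {
        elems[[cur]]$props <- c(elems[[cur]]$props, w[3])
        elems[[cur]]$types <- c(elems[[cur]]$types, w[2])
      }
    }
  }
  if (!"vertex" %in% names(elems)) stop("PLY has no vertex element")
  ve <- elems$vertex
  if (any(grepl("^list:", ve$props)))
    stop("list properties on vertices are not supported")
  nV <- ve$n
  vals <- matrix(NA_real_, nV, length(ve$props))
  if (binary) {
    if (names(elems)[1] != "vertex")
      stop("binary PLY with vertex not first is not supported")
    sizes <- .plyTypeSize[ve$types]
    if (anyNA(sizes)) stop("unknown PLY property type")
    for (i in seq_len(nV)) {
      for (j in seq_along(ve$props)) {
        tp <- ve$types[j]
        vals[i, j] <- switch(tp,
          float = , float32 = readBin(con, "numeric", 1L, size = 4L,
                                      endian = "little"),
          double = , float64 = readBin(con, "numeric", 1L, size = 8L,
                                       endian = "little"),
          uchar = , uint8 = , char = , int8 =
            readBin(con, "integer", 1L, size = 1L, signed = FALSE,
                    endian = "little"),
          readBin(con, "integer", 1L, size = sizes[j], endian = "little"))
      }
    }
  } else {
    txt <- readLines(con, n = -1L)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nV) stop("truncated ASCII PLY")
    sp <- strsplit(trimws(txt[seq_len(nV)]), "\\s+")
    vals <- t(vapply(sp, function(v)
      as.numeric(v[seq_along(ve$props)]), numeric(length(ve$props))))
  }
  colnames(vals) <- ve$props
  need <- c("x", "y", "z")
  if (!all(need %in% ve$props)) stop("PLY vertex element lacks x/y/z")
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% ve$props))
    normals <- unname(vals[, c("nx", "ny", "nz"), drop = FALSE])
  SurfacePointCloud(unname(vals[, need, drop = FALSE]), normals = normals)
}

#' Write a point cloud as PLY
#'
#' @param cloud a \linkS4class{SurfacePointCloud}.
#' @param path output path.
#' @param binary write binary_little_endian (default FALSE = ASCII).
#' @export
writePLY <- function(cloud, path, binary = FALSE) {
  P <- coords(cloud)
  hasN <- nrow(cloud@normals) == nrow(P)
  props <- c("x", "y", "z", if (hasN) c("nx", "ny", "nz"))
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0"
           else "format ascii 1.0",
           sprintf("element vertex %d", nrow(P)),
           sprintf("property float %s", props),
           "end_header")
  M <- if (hasN) cbind(P, cloud@normals) else P
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(t(M)), con, size = 4L, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(M, 1, function(v)
      paste(sprintf("%.6f", v), collapse = " ")), con)
  }
  invisible(path)
}

#' Read vertices from an OBJ file
#'
#' @param path OBJ file path.
#' @return a \linkS4class{SurfacePointCloud} (faces ignored).
#' @export
readOBJ <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  if (!length(vl)) stop("no vertices in OBJ file")
  sp <- strsplit(trimws(vl), "\\s+")
  P <- t(vapply(sp, function(v) as.numeric(v[2:4]), numeric(3)))
  SurfacePointCloud(P)
}

#' Write a point cloud as OBJ vertices
#'
#' @param cloud a \linkS4class{SurfacePointCloud}.
#' @param path output path.
#' @export
writeOBJ <- function(cloud, path) {
  P <- coords(cloud)
  writeLines(sprintf("v %.6f %.6f %.6f", P[, 1], P[, 2], P[, 3]), path)
  invisible(path)
}

#' Landmark CSV/JSON I/O
#'
#' CSV columns: name, x_mm, y_mm, z_mm.  JSON: an object mapping names to
#' [x, y, z] arrays.
#'
#' @param path file path.
#' @return a \linkS4class{LandmarkSet} (readers) or the path (writers).
#' @export
readLandmarksCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(d[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- d$name
  colnames(m) <- c("x", "y", "z")
  LandmarkSet(m)
}

#' @rdname readLandmarksCSV
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @export
writeLandmarksCSV <- function(landmarks, path) {
  cc <- coords(landmarks)
  utils::write.csv(data.frame(name = rownames(cc), x_mm = cc[, 1],
                              y_mm = cc[, 2], z_mm = cc[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname readLandmarksCSV
#' @export
readLandmarksJSON <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- do.call(rbind, d)
  rownames(m) <- names(d)
  LandmarkSet(m)
}

#' @rdname readLandmarksCSV
#' @export
writeLandmarksJSON <- function(landmarks, path) {
  cc <- coords(landmarks)
  obj <- stats::setNames(lapply(seq_len(nrow(cc)), function(i)
    unname(cc[i, ])), rownames(cc))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Ground-truth / boundary curve CSV I/O
#'
#' Columns: curve_id, x_mm, y_mm, z_mm.
#'
#' @param curves named list of polyline matrices (n x 3).
#' @param path file path.
#' @export
writeCurvesCSV <- function(curves, path) {
  rows <- lapply(names(curves), function(nm) {
    M <- as.matrix(curves[[nm]])
    data.frame(curve_id = nm, x_mm = M[, 1], y_mm = M[, 2], z_mm = M[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCurvesCSV
#' @export
readCurvesCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$curve_id), function(g)
    unname(as.matrix(g[, c("x_mm", "y_mm", "z_mm")])))
}
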