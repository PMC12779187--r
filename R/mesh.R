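# Optional mesh-level utilities: reading labelled triangle meshes and
# reducing them to per-tooth centroid tables. Feature extraction itself
# operates on centroids, so these are front-end conveniences.

#' Read an ASCII PLY mesh with per-face tooth labels
#'
#' Expects the standard `element vertex` block with `x`, `y`, `z` properties
#' and an `element face` block with a `vertex_indices` list property plus one
#' integer per-face property (e.g. `label`) carrying the FDI code (0 =
#' unlabelled gingiva).
#'
#' @param path PLY file path.
#' @return list with `vertices` (V x 3), `faces` (F x 3, 1-based) and
#'   `labels` (integer per face).
#' @export
readLabeledPly <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") .stopf("not a PLY file: %s", path)
  endH <- which(trimws(lines) == "end_header")[1]
  if (is.na(endH)) .stopf("PLY header not terminated")
  header <- lines[seq_len(endH)]
  if (!any(grepl("^format ascii", trimws(header))))
    .stopf("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) .stopf("missing vertex/face elements")

  body <- lines[(endH + 1):length(lines)]
  vtx <- do.call(rbind, lapply(body[seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  faceLines <- body[nv + seq_len(nf)]
  parsed <- lapply(faceLines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  faces <- t(vapply(parsed, function(p) p[2:(1 + p[1])][1:3] + 1, numeric(3)))
  labels <- vapply(parsed, function(p) {
    if (length(p) > 1 + p[1]) as.integer(p[2 + p[1]]) else 0L
  }, integer(1))
  list(vertices = vtx, faces = faces, labels = labels)
}

#' Read an OBJ mesh with FDI-coded face groups
#'
#' Faces inherit the FDI code parsed from the most recent `g <code>` line
#' (non-numeric group names map to 0 = unlabelled).
#'
#' @param path OBJ file path.
#' @return same structure as [readLabeledPly()].
#' @export
readLabeledObj <- function(path) {
  lines <- trimws(readLines(path))
  vl <- grep("^v\\s", lines, value = TRUE)
  vtx <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][2:4])))
  cur <- 0L
  faces <- list(); labels <- integer()
  for (l in lines) {
    if (startsWith(l, "g ")) {
      g <- suppressWarnings(as.integer(sub("^g\\s+", "", l)))
      cur <- if (is.na(g)) 0L else g
    } else if (startsWith(l, "f ")) {
      toks <- strsplit(l, "\\s+")[[1]][-1]
      idx <- as.integer(vapply(strsplit(toks, "/"), `[`, character(1), 1))
      faces[[length(faces) + 1L]] <- idx[1:3]
      labels <- c(labels, cur)
    }
  }
  list(vertices = vtx, faces = do.call(rbind, faces), labels = labels)
}

.faceAreasCentroids <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  d <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind((b[, 2] - a[, 2]) * (d[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (d[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (d[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (d[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (d[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (d[, 1] - a[, 1]))
  list(area = 0.5 * sqrt(rowSums(cr^2)), centroid = (a + b + d) / 3)
}

#' Reduce a labelled mesh to a per-tooth centroid arch
#'
#' Each labelled tooth's centroid is the area-weighted mean of its faces'
#' centroids; label 0 (gingiva / unlabelled) is ignored.
#'
#' @param mesh list as returned by [readLabeledPly()] / [readLabeledObj()].
#' @param archId `"maxilla"` or `"mandible"`.
#' @return a [ToothArch-class].
#' @export
archFromMesh <- function(mesh, archId) {
  fc <- .faceAreasCentroids(mesh)
  keep <- mesh$labels > 0
  labs <- mesh$labels[keep]
  ctr <- vapply(sort(unique(labs)), function(code) {
    sel <- which(keep)[labs == code]
    w <- fc$area[sel]
    colSums(fc$centroid[sel, , drop = FALSE] * w) / sum(w)
  }, numeric(3))
  m <- t(ctr)
  rownames(m) <- as.character(sort(unique(labs)))
  colnames(m) <- c("x", "y", "z")
  toothArch(archId, m)
}

#' Decimate a labelled triangle mesh by vertex clustering
#'
#' Collapses vertices falling in the same cell of a uniform grid and drops
#' degenerate faces; the grid size is grown until the face count is at or
#' below `targetFaces`. Surviving faces keep their labels. A coarse utility
#' for taming raw scan meshes before centroid extraction.
#'
#' @param mesh labelled mesh list.
#' @param targetFaces maximum face count (default 16000).
#' @return decimated mesh list.
#' @export
decimateMesh <- function(mesh, targetFaces = 16000) {
  if (nrow(mesh$faces) <= targetFaces) return(mesh)
  bb <- apply(mesh$vertices, 2, range)
  diam <- max(bb[2, ] - bb[1, ])
  cell <- diam / 256
  for (iter in 1:24) {
    key <- floor(sweep(mesh$vertices, 2, bb[1, ]) / cell)
    id <- paste(key[, 1], key[, 2], key[, 3])
    map <- match(id, unique(id))
    newV <- apply(mesh$vertices, 2, function(col) tapply(col, map, mean))
    f <- matrix(map[mesh$faces], ncol = 3)
    ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    if (sum(ok) <= targetFaces)
      return(list(vertices = newV, faces = f[ok, , drop = FALSE],
                  labels = mesh$labels[ok]))
    cell <- cell * 1.5
  }
  .stopf("decimation failed to reach %d faces", targetFaces)
}
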