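# Plain-text interchange: landmark tables, bounding-box tables, feature
# matrices and padding sidecars.

#' Read a landmark CSV (image_id, index, x, y)
#'
#' @param path CSV path.
#' @return named list of [LandmarkSet-class], one per image id.
#' @export
readLandmarksCsv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("image_id", "index", "x", "y")
  if (!all(need %in% names(tab)))
    .stopf("landmark CSV must have columns %s", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$image_id), function(d)
    landmarkSet(as.matrix(d[order(d$index), c("x", "y")])))
  out[unique(as.character(tab$image_id))]
}

#' Write pairwise-angle features for a set of landmark sets
#'
#' One row per image, columns `ang_i_j`.
#'
#' @param landmarks named list of [LandmarkSet-class].
#' @param path output CSV path.
#' @return the feature matrix, invisibly.
#' @export
writeAngleFeaturesCsv <- function(landmarks, path) {
  rows <- lapply(landmarks, pairwiseAngles)
  m <- do.call(rbind, rows)
  utils::write.csv(data.frame(image_id = names(landmarks), m,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(m)
}

#' Read a bounding-box CSV (image_id, x_min, y_min, x_max, y_max)
#'
#' @param path CSV path.
#' @return named list of numeric(4) boxes.
#' @export
readBboxCsv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(tab)))
    .stopf("bbox CSV must have columns %s", paste(need, collapse = ", "))
  stats::setNames(lapply(seq_len(nrow(tab)), function(i)
    as.numeric(tab[i, c("x_min", "y_min", "x_max", "y_max")])),
    as.character(tab$image_id))
}

#' Write a feature matrix to CSV with a subject id column
#'
#' @param features subjects x features matrix with rownames.
#' @param path output CSV path.
#' @export
writeFeaturesCsv <- function(features, path) {
  utils::write.csv(data.frame(subject_id = rownames(features), features,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [writeFeaturesCsv()]
#'
#' @param path CSV path.
#' @return subjects x features matrix with subject ids as rownames.
#' @export
readFeaturesCsv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Write the padding/scale sidecar of a standardised image
#'
#' Records the metadata needed to invert detector-space bounding boxes back
#' to the original image.
#'
#' @param image a [GrayImage-class] from [standardizeCeph()].
#' @param path output JSON path.
#' @export
writeImageSidecar <- function(image, path) {
  jsonlite::write_json(image@meta, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a padding/scale sidecar
#'
#' @param path JSON path.
#' @return metadata list usable with [unprojectBbox()].
#' @export
readImageSidecar <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
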