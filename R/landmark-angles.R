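# Pairwise angular featurisation of 2D cephalometric landmarks: for every
# unordered pair (i < j) the orientation of the displacement i -> j relative
# to the x-axis. 29 landmarks give C(29, 2) = 406 angles. The representation
# is exactly translation- and scale-invariant, and a global rotation shifts
# every angle by the same amount.

#' Pairwise orientation angles of a landmark configuration
#'
#' For each pair `i < j` (lexicographic order) the two-argument arctangent
#' `atan2(y_j - y_i, x_j - x_i)`, range `(-pi, pi]`. The single-argument
#' arctangent of the slope is undefined for vertical pairs, so the directed
#' two-argument form is the default; `convention = "undirected"` folds angles
#' onto `(-pi/2, pi/2]` (mod pi), treating i -> j and j -> i as the same
#' line.
#'
#' @param landmarks a [LandmarkSet-class] or an n x 2 coordinate matrix.
#' @param convention `"directed"` (default, atan2 range) or `"undirected"`
#'   (mod-pi line orientation).
#' @return named numeric of length `choose(n, 2)`; names `ang_i_j`.
#' @examples
#' pts <- cbind(runif(29, 0, 256), runif(29, 0, 256))
#' length(pairwiseAngles(landmarkSet(pts)))   # 406
#' @export
setGeneric("pairwiseAngles",
           function(landmarks, convention = c("directed", "undirected"))
             standardGeneric("pairwiseAngles"))

#' @rdname pairwiseAngles
setMethod("pairwiseAngles", "LandmarkSet", function(landmarks, convention) {
  pairwiseAngles(landmarks@points, convention)
})

#' @rdname pairwiseAngles
setMethod("pairwiseAngles", "matrix", function(landmarks, convention) {
  convention <- match.arg(convention, c("directed", "undirected"))
  n <- nrow(landmarks)
  if (n < 2) .stopf("need at least 2 landmarks")
  if (!all(is.finite(landmarks))) .stopf("non-finite landmark coordinates")
  pairs <- utils::combn(n, 2)
  dx <- landmarks[pairs[2, ], 1] - landmarks[pairs[1, ], 1]
  dy <- landmarks[pairs[2, ], 2] - landmarks[pairs[1, ], 2]
  deg <- which(dx == 0 & dy == 0)
  if (length(deg))
    .stopf("degenerate pair: coincident landmarks (%d, %d)",
           pairs[1, deg[1]], pairs[2, deg[1]])
  ang <- atan2(dy, dx)
  if (convention == "undirected") {
    ang <- ang %% pi
    ang[ang > pi / 2] <- ang[ang > pi / 2] - pi   # fold to (-pi/2, pi/2]
  }
  names(ang) <- paste0("ang_", pairs[1, ], "_", pairs[2, ])
  ang
})

#' Wrap angles to the interval (-pi, pi]
#'
#' @param x numeric angles in radians.
#' @return wrapped angles.
#' @export
wrapAngle <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}
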