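# Arch-level geometric features: the four standard orthodontic measurements
# and the two centroid-distance features (to the arch center and to a
# quadratic Bezier curve anchored on the second molars and central incisors).

#' Rigidly normalise an arch into a canonical anatomical frame
#'
#' The best-fit plane of the tooth centroids is mapped to Z = 0, the
#' anteroposterior axis (second-molar midpoint towards central-incisor
#' midpoint) to +Y, the left-to-right transverse axis to +X, and the origin is
#' placed at the projection of the central-incisor midpoint onto the best-fit
#' plane. The transform is rigid: pairwise centroid distances are preserved.
#'
#' @param arch a [ToothArch-class] containing at least the two second molars
#'   and the two central incisors, with >= 3 non-collinear centroids.
#' @return a `ToothArch` in canonical pose.
#' @export
setGeneric("normalizeArch", function(arch) standardGeneric("normalizeArch"))

#' @rdname normalizeArch
setMethod("normalizeArch", "ToothArch", function(arch) {
  P <- arch@centroids
  if (nrow(P) < 3) .stopf("need >= 3 centroids to normalise an arch")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    .stopf("degenerate geometry: centroids are collinear")
  n <- sv$v[, 3]                       # best-fit plane normal

  m2 <- .fdiPair(arch@archId, 7L)
  i1 <- .fdiPair(arch@archId, 1L)
  .need <- function(codes) {
    miss <- setdiff(as.character(codes), rownames(P))
    if (length(miss)) .stopf("missing tooth FDI %s", paste(miss, collapse = ", "))
  }
  .need(m2); .need(i1)
  molarMid   <- (P[as.character(m2["left"]), ] + P[as.character(m2["right"]), ]) / 2
  incisorMid <- (P[as.character(i1["left"]), ] + P[as.character(i1["right"]), ]) / 2

  yAxis <- incisorMid - molarMid
  yAxis <- .unit(yAxis - sum(yAxis * n) * n)          # in-plane AP axis
  xRaw  <- P[as.character(m2["right"]), ] - P[as.character(m2["left"]), ]
  xRaw  <- xRaw - sum(xRaw * n) * n
  xAxis <- .unit(xRaw - sum(xRaw * yAxis) * yAxis)    # in-plane transverse axis
  zAxis <- .cross3(xAxis, yAxis)                      # right-handed frame
  R <- cbind(xAxis, yAxis, zAxis)

  # origin: incisor midpoint projected onto the best-fit plane (through ctr)
  origin <- incisorMid - sum((incisorMid - ctr) * zAxis) * zAxis
  Q <- sweep(P, 2, origin) %*% R
  dimnames(Q) <- dimnames(P)
  colnames(Q) <- c("x", "y", "z")
  new("ToothArch", archId = arch@archId, centroids = Q)
})

#' Arch center
#'
#' The unweighted mean of the tooth centroids; the reference point for the
#' centroid-to-center distance features.
#'
#' @param arch a [ToothArch-class] with at least one tooth.
#' @return numeric(3) point in mm.
#' @export
setGeneric("archCenter", function(arch) standardGeneric("archCenter"))

#' @rdname archCenter
setMethod("archCenter", "ToothArch", function(arch) {
  if (nrow(arch@centroids) < 1) .stopf("empty arch")
  colMeans(arch@centroids)
})

.toothRow <- function(arch, code) {
  key <- as.character(code)
  if (!key %in% rownames(arch@centroids))
    .stopf("missing tooth FDI %s", key)
  arch@centroids[key, ]
}

#' Standard orthodontic arch measurements
#'
#' Inter-canine width (canine-to-canine centroid distance), inter-molar width
#' (first molars), arch depth (perpendicular distance from the central-incisor
#' contact midpoint to the second-molar line), and total arch length (polyline
#' through the centroids in anatomical order, left second molar to right
#' second molar).
#'
#' @param arch a [ToothArch-class] with the full 14-tooth complement (at
#'   minimum both canines, first molars, second molars and central incisors).
#' @return named numeric: `arch_length`, `inter_molar_width`,
#'   `inter_canine_width`, `arch_depth` (mm).
#' @export
setGeneric("standardMeasurements", function(arch) standardGeneric("standardMeasurements"))

#' @rdname standardMeasurements
setMethod("standardMeasurements", "ToothArch", function(arch) {
  id <- arch@archId
  canine <- .fdiPair(id, 3L); molar1 <- .fdiPair(id, 6L)
  molar2 <- .fdiPair(id, 7L); inc1 <- .fdiPair(id, 1L)
  d <- function(a, b) sqrt(sum((a - b)^2))

  icw <- d(.toothRow(arch, canine["left"]), .toothRow(arch, canine["right"]))
  imw <- d(.toothRow(arch, molar1["left"]), .toothRow(arch, molar1["right"]))

  mL <- .toothRow(arch, molar2["left"]); mR <- .toothRow(arch, molar2["right"])
  incMid <- (.toothRow(arch, inc1["left"]) + .toothRow(arch, inc1["right"])) / 2
  axis <- mR - mL
  if (sqrt(sum(axis^2)) < 1e-12) .stopf("degenerate geometry: coincident second molars")
  u <- .unit(axis)
  w <- incMid - mL
  depth <- sqrt(max(sum(w^2) - sum(w * u)^2, 0))

  ord <- as.character(.fdiOrder(id))
  present <- ord[ord %in% rownames(arch@centroids)]
  if (length(present) < 2) .stopf("need >= 2 teeth for arch length")
  pts <- arch@centroids[present, , drop = FALSE]
  segs <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(arch_length = sum(segs), inter_molar_width = imw,
    inter_canine_width = icw, arch_depth = depth)
})

#' Evaluate a quadratic Bezier curve
#'
#' @param curve a [QuadraticBezier-class].
#' @param t parameter values in `[0, 1]`.
#' @return matrix `length(t)` x 3 of curve points.
#' @export
bezierPoint <- function(curve, t) {
  t <- as.numeric(t)
  b0 <- (1 - t)^2; b1 <- 2 * t * (1 - t); b2 <- t^2
  out <- outer(b0, curve@p0) + outer(b1, curve@p1) + outer(b2, curve@p2)
  if (length(t) == 1) drop(out) else out
}

#' Fit the arch Bezier curve through second molars and central incisors
#'
#' p0 and p2 are the left and right second-molar centroids; p1 is the unique
#' middle control point for which the curve midpoint B(1/2) coincides with the
#' midpoint of the two central-incisor centroids: p1 = 2 M - (p0 + p2) / 2.
#'
#' @param arch a [ToothArch-class] containing both second molars and both
#'   central incisors.
#' @return a [QuadraticBezier-class] interpolating the three anchors.
#' @export
setGeneric("fitArchBezier", function(arch) standardGeneric("fitArchBezier"))

#' @rdname fitArchBezier
setMethod("fitArchBezier", "ToothArch", function(arch) {
  m2 <- .fdiPair(arch@archId, 7L); i1 <- .fdiPair(arch@archId, 1L)
  p0 <- .toothRow(arch, m2["left"]); p2 <- .toothRow(arch, m2["right"])
  M  <- (.toothRow(arch, i1["left"]) + .toothRow(arch, i1["right"])) / 2
  quadraticBezier(p0, 2 * M - (p0 + p2) / 2, p2)
})

#' Minimum distance from a point to a quadratic Bezier curve
#'
#' Dense parameter sampling over `[0, 1]` followed by local refinement of
#' every sampled local minimum (the squared distance to a quadratic curve has
#' at most three interior critical points, so refining all sampled minima
#' finds the global one).
#'
#' @param point numeric(3).
#' @param curve a [QuadraticBezier-class].
#' @param tol positive distance tolerance in mm (default 1e-6).
#' @param nGrid dense-grid size (default 257).
#' @return minimum Euclidean distance in mm.
#' @export
distanceToBezier <- function(point, curve, tol = 1e-6, nGrid = 257) {
  if (!is.numeric(tol) || length(tol) != 1 || tol <= 0) .stopf("tol must be > 0")
  point <- as.numeric(point)
  f <- function(t) {
    B <- bezierPoint(curve, t)
    if (is.matrix(B)) sqrt(rowSums(sweep(B, 2, point)^2))
    else sqrt(sum((B - point)^2))
  }
  tg <- seq(0, 1, length.out = nGrid)
  dg <- f(tg)
  # local minima of the sampled profile (including endpoints)
  interior <- which(dg[2:(nGrid - 1)] <= dg[1:(nGrid - 2)] &
                    dg[2:(nGrid - 1)] <= dg[3:nGrid]) + 1L
  best <- min(dg[1], dg[nGrid])
  h <- tg[2] - tg[1]
  for (i in interior) {
    opt <- stats::optimize(f, lower = max(0, tg[i] - h), upper = min(1, tg[i] + h),
                           tol = min(tol, 1e-9))
    best <- min(best, opt$objective)
  }
  best
}

#' Per-tooth distance features for one arch
#'
#' Distances from each tooth centroid to the arch center and to the fitted
#' arch Bezier curve, in anatomical order.
#'
#' @param arch a [ToothArch-class].
#' @param tol Bezier distance tolerance (mm).
#' @return list with named numeric vectors `to_center` and `to_bezier`.
#' @export
archDistanceFeatures <- function(arch, tol = 1e-6) {
  ctr <- archCenter(arch)
  curve <- fitArchBezier(arch)
  ord <- as.character(.fdiOrder(arch@archId))
  ord <- ord[ord %in% rownames(arch@centroids)]
  toCenter <- vapply(ord, function(k)
    sqrt(sum((arch@centroids[k, ] - ctr)^2)), numeric(1))
  toBezier <- vapply(ord, function(k)
    distanceToBezier(arch@centroids[k, ], curve, tol = tol), numeric(1))
  list(to_center = toCenter, to_bezier = toBezier)
}

#' Full intraoral-scan feature vector for one subject
#'
#' Concatenates, per arch (maxilla then mandible), the four standard
#' measurements followed by the 14 centroid-to-center distances and the 14
#' centroid-to-Bezier distances, each in anatomical order: 32 features per
#' arch, 64 per subject. Arches are normalised to the canonical frame first;
#' all features are rigid-motion invariant.
#'
#' @param maxilla,mandible [ToothArch-class] objects with the 14-tooth
#'   complement.
#' @param tol Bezier distance tolerance (mm).
#' @return named numeric(64); names like `mx_arch_length`, `mx_ctr_dist_21`,
#'   `md_bez_dist_47`.
#' @export
extractIosFeatures <- function(maxilla, mandible, tol = 1e-6) {
  one <- function(arch, prefix) {
    arch <- normalizeArch(arch)
    sm <- standardMeasurements(arch)
    dd <- archDistanceFeatures(arch, tol = tol)
    out <- c(sm, dd$to_center, dd$to_bezier)
    names(out) <- c(paste0(prefix, "_", names(sm)),
                    paste0(prefix, "_ctr_dist_", names(dd$to_center)),
                    paste0(prefix, "_bez_dist_", names(dd$to_bezier)))
    out
  }
  c(one(maxilla, "mx"), one(mandible, "md"))
}
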