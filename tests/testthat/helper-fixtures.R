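# Shared fixtures, all generated in code.

# symmetric planar arch in canonical pose: teeth on a parabola in the XY
# plane, anterior at +Y, incisor midpoint at the origin
makeIdealArch <- function(archId = "maxilla", halfWidth = 27, depth = 42) {
  codes <- switch(archId,
    maxilla  = c(27, 26, 25, 24, 23, 22, 21, 11, 12, 13, 14, 15, 16, 17),
    mandible = c(37, 36, 35, 34, 33, 32, 31, 41, 42, 43, 44, 45, 46, 47))
  xs <- seq(-halfWidth, halfWidth, length.out = 14)
  ys <- depth * (1 - (xs / halfWidth)^2)
  cm <- cbind(x = xs, y = ys - max(ys), z = 0)     # incisor region near origin
  rownames(cm) <- as.character(codes)
  # shift so the central-incisor midpoint is exactly at the origin
  mid <- (cm[7, ] + cm[8, ]) / 2
  cm <- sweep(cm, 2, mid)
  toothArch(archId, cm)
}

randomRotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigidTransform <- function(arch, R, t) {
  cm <- arch@centroids %*% t(R)
  cm <- sweep(cm, 2, -t)
  colnames(cm) <- c("x", "y", "z")
  toothArch(arch@archId, cm)
}

# independent closed-form oracle for point-to-quadratic-Bezier distance:
# the squared distance is a quartic in t, so its derivative is a cubic whose
# real roots in [0, 1] plus the endpoints carry the global minimum
bezierDistanceCubicOracle <- function(point, curve) {
  A <- curve@p0 - 2 * curve@p1 + curve@p2
  B <- 2 * (curve@p1 - curve@p0)
  C <- curve@p0 - point
  # d/dt |A t^2 + B t + C|^2 / 2 = 2 A.A t^3 + 3 A.B t^2 + (B.B + 2 A.C) t + B.C
  co <- c(sum(B * C), sum(B * B) + 2 * sum(A * C), 3 * sum(A * B), 2 * sum(A * A))
  ts <- c(0, 1)
  if (any(co[2:4] != 0)) {
    r <- polyroot(co)
    re <- Re(r)[abs(Im(r)) < 1e-8]
    ts <- c(ts, re[re > 0 & re < 1])
  }
  min(vapply(ts, function(t) sqrt(sum((A * t^2 + B * t + C)^2)), numeric(1)))
}

# small synthetic cohort with IOS features, cached per options so repeated
# tests in one run reuse it
.cohortCache <- new.env(parent = emptyenv())
cachedIosCohort <- function(n, arch_effect, noise_sd_arch, seed) {
  key <- paste(n, arch_effect, noise_sd_arch, seed, sep = "_")
  if (is.null(.cohortCache[[key]])) {
    coh <- generateCohort(synthConfig(n, arch_effect = arch_effect,
                                      noise_sd_arch = noise_sd_arch,
                                      seed = seed),
                          what = "arches")
    .cohortCache[[key]] <- list(
      ios = cohortIosFeatures(coh), labels = cohortLabels(coh))
  }
  .cohortCache[[key]]
}
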