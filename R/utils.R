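# Internal helpers shared across modules.

#' Round half away from zero at a fixed number of decimals
#'
#' Printed diagnostic tables round half-up (0.875 -> 0.88), unlike base R's
#' banker's rounding, so table matching uses this convention.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @importFrom withr with_seed
NULL

# Derive a per-subject substream seed from a cohort seed. Kept below 2^31 so
# set.seed() accepts it; multiplier is a prime to decorrelate neighbours.
.substreamSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 1009) %% 2147483629L)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# FDI tooth codes in anatomical (left second molar -> right second molar)
# walking order, 14-tooth complement.
.fdiOrder <- function(archId) {
  switch(archId,
    maxilla  = c(27L, 26L, 25L, 24L, 23L, 22L, 21L, 11L, 12L, 13L, 14L, 15L, 16L, 17L),
    mandible = c(37L, 36L, 35L, 34L, 33L, 32L, 31L, 41L, 42L, 43L, 44L, 45L, 46L, 47L),
    .stopf("unknown arch id '%s' (expected 'maxilla' or 'mandible')", archId)
  )
}

# left/right members of a tooth-type pair (type = last FDI digit)
.fdiPair <- function(archId, type) {
  q <- switch(archId, maxilla = c(2L, 1L), mandible = c(3L, 4L))
  c(left = q[1] * 10L + type, right = q[2] * 10L + type)
}

.validFdi <- function(archId) .fdiOrder(archId)

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) .stopf("degenerate geometry: zero-length direction vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
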