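# Separable bicubic (Catmull-Rom, a = -0.5) resampling. Implemented as two
# dense weight-matrix products so resizes are deterministic and fast; edge
# samples are clamped. The Catmull-Rom dialect is the common imaging default,
# recorded here because bicubic variants differ.

.catmullRom <- function(t) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- 1.5 * at[i1]^3 - 2.5 * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- -0.5 * at[i2]^3 + 2.5 * at[i2]^2 - 4 * at[i2] + 2
  w
}

.resampleWeights <- function(nIn, nOut) {
  scale <- nIn / nOut
  src <- (seq_len(nOut) - 0.5) * scale - 0.5      # 0-based source coordinate
  base <- floor(src)
  W <- matrix(0, nOut, nIn)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 0), nIn - 1) + 1   # clamp to edge
    w <- .catmullRom(src - (base + k))
    W[cbind(seq_len(nOut), idx)] <- W[cbind(seq_len(nOut), idx)] + w
  }
  W
}

#' Bicubic (Catmull-Rom) image resize
#'
#' @param pixels numeric matrix.
#' @param outH,outW output dimensions.
#' @param clip clip the (possibly overshooting) cubic output to `[0, 1]`.
#' @return resized matrix.
#' @export
resizeBicubic <- function(pixels, outH, outW, clip = TRUE) {
  Wr <- .resampleWeights(nrow(pixels), outH)
  Wc <- .resampleWeights(ncol(pixels), outW)
  out <- Wr %*% pixels %*% t(Wc)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}
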