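# Spatial pyramid pooling: nested grid partitions of the latent map pooled
# per cell and per channel into one fixed-length descriptor. Grids
# [1x1],[2x2],[4x4],[8x8] over a 4-channel map give 1+4+16+64 = 85 regions
# x 4 channels = 340 values.

#' Spatial pyramid pooling of a latent map
#'
#' Each pyramid level `g` partitions the H x W map into a `g x g` grid of
#' equal cells and pools every cell per channel with `op`. Values are
#' concatenated coarse to fine, cells in row-major order, channels varying
#' fastest within a cell, giving `sum(g^2) * C` values independent of the map
#' size.
#'
#' @param latent numeric array `(H, W, C)`; H and W must be divisible by
#'   every level (the canonical latent is 32 x 32 x 4).
#' @param levels integer grid sizes (default `c(1, 2, 4, 8)`).
#' @param op `"max"` (default, classical SPP) or `"mean"`.
#' @return numeric vector of length `sum(levels^2) * C` (340 for the
#'   defaults).
#' @examples
#' toy <- array(c(1, 3, 2, 4), c(2, 2, 1))   # [[1,2],[3,4]] row-major
#' spatialPyramidPool(toy, levels = c(1, 2)) # 4 1 2 3 4
#' @export
spatialPyramidPool <- function(latent, levels = c(1, 2, 4, 8),
                               op = c("max", "mean")) {
  op <- match.arg(op)
  if (!is.array(latent) || length(dim(latent)) != 3)
    .stopf("latent must be a 3D array (H, W, C)")
  d <- dim(latent)
  H <- d[1]; W <- d[2]; C <- d[3]
  bad <- levels[H %% levels != 0 | W %% levels != 0]
  if (length(bad))
    .stopf("latent %dx%d is not divisible by pyramid level %d", H, W, bad[1])
  pool <- if (op == "max") max else mean
  out <- numeric(sum(levels^2) * C)
  pos <- 1L
  for (g in levels) {
    ch <- H %/% g; cw <- W %/% g
    for (gi in seq_len(g)) for (gj in seq_len(g)) {
      rows <- ((gi - 1) * ch + 1):(gi * ch)
      cols <- ((gj - 1) * cw + 1):(gj * cw)
      for (cc in seq_len(C)) {
        out[pos] <- pool(latent[rows, cols, cc])
        pos <- pos + 1L
      }
    }
  }
  out
}

#' Number of pooled regions for a set of pyramid levels
#'
#' @param levels integer grid sizes.
#' @return total region count (85 for levels 1, 2, 4, 8).
#' @export
sppRegionCount <- function(levels = c(1, 2, 4, 8)) sum(levels^2)
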