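# Deterministic standardisation chain for lateral-cephalogram-like images:
# histogram equalisation, zero-padding to square, bicubic resize to the
# 240x240 detector space, bounding-box inversion back to the original image,
# crop + resize to 256x256, and a seeded augmentation chain.

#' Global 256-bin histogram equalisation
#'
#' @param pixels numeric matrix in `[0, 1]`. Constant images are returned
#'   unchanged (their histogram cannot be equalised).
#' @param levels number of histogram bins.
#' @return equalised matrix in `[0, 1]`.
#' @export
histogramEqualize <- function(pixels, levels = 256) {
  if (length(unique(as.vector(pixels))) < 2) return(pixels)
  EBImage::equalize(pixels, range = c(0, 1), levels = levels)
}

.toUnit <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1 || ncol(pixels) < 1) .stopf("empty image")
  if (!all(is.finite(pixels))) .stopf("non-finite pixel values")
  mx <- max(pixels)
  if (mx > 1) pixels <- pixels / if (mx <= 255) 255 else mx
  pmin(pmax(pixels, 0), 1)
}

#' Standardise a raw grayscale image into the 240x240 detector space
#'
#' Histogram equalisation, symmetric zero-padding to square (any odd
#' remainder goes to the bottom/right), bicubic resize to
#' `size` x `size`, intensities in `[0, 1]`. The padding/scale record needed
#' to invert bounding boxes is stored in the result's metadata.
#'
#' @param pixels raw grayscale matrix; 8-bit inputs (max > 1) are rescaled to
#'   `[0, 1]`.
#' @param size detector-space side length (default 240).
#' @param equalize apply histogram equalisation first (default TRUE).
#' @return a [GrayImage-class] with `meta` fields `orig_h`, `orig_w`,
#'   `pad_top`, `pad_left`, `square_side`, `out_size`.
#' @export
standardizeCeph <- function(pixels, size = 240, equalize = TRUE) {
  pixels <- .toUnit(pixels)
  if (nrow(pixels) < 1 || ncol(pixels) < 1) .stopf("empty image")
  if (equalize) pixels <- histogramEqualize(pixels)

  h <- nrow(pixels); w <- ncol(pixels)
  side <- max(h, w)
  padTop <- floor((side - h) / 2); padBottom <- side - h - padTop
  padLeft <- floor((side - w) / 2); padRight <- side - w - padLeft
  sq <- matrix(0, side, side)
  sq[padTop + seq_len(h), padLeft + seq_len(w)] <- pixels

  out <- resizeBicubic(sq, size, size)
  grayImage(out, meta = list(orig_h = h, orig_w = w, pad_top = padTop,
                             pad_left = padLeft, square_side = side,
                             out_size = size))
}

.checkBox <- function(box) {
  box <- as.numeric(box)
  if (length(box) != 4 || !all(is.finite(box)))
    .stopf("box must be numeric (x_min, y_min, x_max, y_max)")
  if (box[1] >= box[3] || box[2] >= box[4]) .stopf("empty crop: degenerate box")
  box
}

#' Map a detector-space bounding box back to original image coordinates
#'
#' Linear rescale by `square_side / out_size`, then subtraction of the pad
#' offsets recorded by [standardizeCeph()]; the result is clipped to the
#' original image bounds.
#'
#' @param box numeric (x_min, y_min, x_max, y_max) in detector space (x =
#'   column, y = row, 0-based continuous coordinates).
#' @param meta metadata list from a standardised image.
#' @return numeric(4) box in original-image coordinates.
#' @export
unprojectBbox <- function(box, meta) {
  box <- .checkBox(box)
  s <- meta$square_side / meta$out_size
  x <- box[c(1, 3)] * s - meta$pad_left
  y <- box[c(2, 4)] * s - meta$pad_top
  x <- pmin(pmax(x, 0), meta$orig_w)
  y <- pmin(pmax(y, 0), meta$orig_h)
  if (x[1] >= x[2] || y[1] >= y[2])
    .stopf("empty crop: box lies outside the image content")
  c(x_min = x[1], y_min = y[1], x_max = x[2], y_max = y[2])
}

#' Forward-map an original-space box into detector space
#'
#' Exact inverse of [unprojectBbox()] on box corners; used for round-trip
#' verification.
#'
#' @inheritParams unprojectBbox
#' @return numeric(4) box in detector-space coordinates.
#' @export
projectBbox <- function(box, meta) {
  box <- .checkBox(box)
  s <- meta$square_side / meta$out_size
  c(x_min = (box[1] + meta$pad_left) / s, y_min = (box[2] + meta$pad_top) / s,
    x_max = (box[3] + meta$pad_left) / s, y_max = (box[4] + meta$pad_top) / s)
}

#' Fallback region-of-interest heuristic
#'
#' When no trained detector box is available: the bounding box of
#' high-gradient pixels (above a quantile threshold), expanded by a margin.
#' This is a stand-in heuristic, not the study's trained detector.
#'
#' @param pixels grayscale matrix in `[0, 1]`.
#' @param q gradient-magnitude quantile defining "high gradient".
#' @param margin fractional margin added on each side.
#' @return numeric(4) box in original-image coordinates.
#' @export
heuristicBbox <- function(pixels, q = 0.9, margin = 0.05) {
  gx <- cbind(pixels[, -1] - pixels[, -ncol(pixels)], 0)
  gy <- rbind(pixels[-1, ] - pixels[-nrow(pixels), ], 0)
  g <- sqrt(gx^2 + gy^2)
  thr <- stats::quantile(g, q)
  idx <- which(g >= thr & g > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(x_min = 0, y_min = 0,
                               x_max = ncol(pixels), y_max = nrow(pixels)))
  mh <- margin * nrow(pixels); mw <- margin * ncol(pixels)
  c(x_min = max(0, min(idx[, 2]) - 1 - mw),
    y_min = max(0, min(idx[, 1]) - 1 - mh),
    x_max = min(ncol(pixels), max(idx[, 2]) + mw),
    y_max = min(nrow(pixels), max(idx[, 1]) + mh))
}

#' Crop a region from the original grayscale image and resize to 256x256
#'
#' @param pixels raw grayscale matrix (rescaled to `[0, 1]` if 8-bit).
#' @param box original-space box (x_min, y_min, x_max, y_max), 0-based
#'   continuous coordinates.
#' @param size output side length (default 256).
#' @return a [GrayImage-class] of shape `size` x `size`.
#' @export
cropResize <- function(pixels, box, size = 256) {
  pixels <- .toUnit(pixels)
  box <- .checkBox(box)
  r0 <- floor(box[2]) + 1; r1 <- ceiling(box[4])
  c0 <- floor(box[1]) + 1; c1 <- ceiling(box[3])
  r0 <- max(1, r0); c0 <- max(1, c0)
  r1 <- min(nrow(pixels), r1); c1 <- min(ncol(pixels), c1)
  if (r1 < r0 || c1 < c0) .stopf("empty crop")
  crop <- pixels[r0:r1, c0:c1, drop = FALSE]
  grayImage(resizeBicubic(crop, size, size),
            meta = list(crop = c(r0, r1, c0, c1), out_size = size))
}

#' Seeded augmentation: rotation / translation / zoom, noise, masking
#'
#' Applied only to training folds. A random similarity transform (bilinear
#' resampling, zero background) emulates head-orientation variability;
#' Gaussian noise emulates detector noise; aggressive masking zeroes square
#' patches until the requested fraction of pixels is occluded. Fully
#' deterministic given `seed`; with all parameters zero the input is returned
#' unchanged.
#'
#' @param image a [GrayImage-class].
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param mask_fraction fraction of pixels to occlude, in `[0, 1)`.
#' @param max_rotation_deg rotation drawn uniformly in +/- this many degrees.
#' @param max_translation_px translation drawn uniformly in +/- this many px.
#' @param zoom_range zoom factor drawn uniformly in 1 +/- `zoom_range`.
#' @param mask_patch side length of masking patches (px).
#' @param seed integer seed.
#' @return augmented [GrayImage-class] of the same shape.
#' @export
augmentImage <- function(image, noise_sd = 0, mask_fraction = 0,
                         max_rotation_deg = 0, max_translation_px = 0,
                         zoom_range = 0, mask_patch = 16, seed = 1) {
  stopifnot(noise_sd >= 0, mask_fraction >= 0, mask_fraction < 1,
            max_rotation_deg >= 0, max_translation_px >= 0, zoom_range >= 0)
  px <- image@pixels
  if (noise_sd == 0 && mask_fraction == 0 && max_rotation_deg == 0 &&
      max_translation_px == 0 && zoom_range == 0)
    return(image)

  withr::with_seed(as.integer(seed), {
    if (max_rotation_deg > 0 || max_translation_px > 0 || zoom_range > 0) {
      ang <- runif(1, -max_rotation_deg, max_rotation_deg) * pi / 180
      tx <- runif(1, -max_translation_px, max_translation_px)
      ty <- runif(1, -max_translation_px, max_translation_px)
      s <- 1 + runif(1, -zoom_range, zoom_range)
      A <- s * matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      ctr <- c(nrow(px), ncol(px)) / 2
      off <- ctr - as.vector(A %*% ctr) + c(ty, tx)
      m <- rbind(t(A), off)          # EBImage: y = cbind(x, 1) %*% m
      px <- EBImage::affine(px, m, filter = "bilinear",
                            output.dim = dim(px), bg.col = 0)
      px <- matrix(as.numeric(px), nrow(image@pixels), ncol(image@pixels))
    }
    if (noise_sd > 0)
      px <- px + matrix(rnorm(length(px), 0, noise_sd), nrow(px))
    if (mask_fraction > 0) {
      mask <- matrix(FALSE, nrow(px), ncol(px))
      patch <- min(mask_patch, nrow(px), ncol(px))
      while (mean(mask) < mask_fraction) {
        r <- sample.int(nrow(px) - patch + 1, 1)
        cc <- sample.int(ncol(px) - patch + 1, 1)
        mask[r:(r + patch - 1), cc:(cc + patch - 1)] <- TRUE
      }
      px[mask] <- 0
    }
  })
  grayImage(pmin(pmax(px, 0), 1), meta = image@meta)
}
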