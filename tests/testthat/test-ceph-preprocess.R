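test_that("standardize pads symmetrically and lands in [0,1] at 240x240", {
  set.seed(1)
  raw <- matrix(runif(100 * 60), 100, 60)
  st <- standardizeCeph(raw)
  expect_equal(dim(imagePixels(st)), c(240, 240))
  expect_gte(min(imagePixels(st)), 0)
  expect_lte(max(imagePixels(st)), 1)
  # (100 - 60) / 2 = 20 zero-columns each side before the resize
  expect_equal(st@meta$pad_left, 20)
  expect_equal(st@meta$pad_top, 0)
  expect_equal(st@meta$square_side, 100)

  # odd remainder goes to the trailing side
  st2 <- standardizeCeph(matrix(runif(9 * 4), 9, 4), size = 24)
  expect_equal(st2@meta$pad_left, 2)          # (9-4)/2 floor = 2, right gets 3

  # identity-size constant input keeps its geometry
  stc <- standardizeCeph(matrix(0.5, 240, 240))
  expect_equal(dim(imagePixels(stc)), c(240, 240))
  expect_equal(unique(as.vector(imagePixels(stc))), 0.5)

  expect_error(standardizeCeph(matrix(numeric(0), 0, 0)), "empty")
})

test_that("standardize is idempotent up to resampling tolerance", {
  set.seed(2)
  raw <- matrix(runif(300 * 200), 300, 200)
  st <- standardizeCeph(raw)
  st2 <- standardizeCeph(imagePixels(st))
  expect_equal(st2@meta$pad_left, 0)
  expect_lt(mean(abs(imagePixels(st2) - imagePixels(st))), 0.05)
})

test_that("bbox unprojection inverts the squaring transform", {
  meta <- standardizeCeph(matrix(runif(100 * 60), 100, 60))@meta

  # spec-style worked case: scale 100/240, then x minus the 20-px pad
  b <- unprojectBbox(c(120, 0, 240, 100), meta)
  expect_equal(unname(b), c(120 * 100 / 240 - 20, 0, 60, 100 * 100 / 240))

  # identity case: no padding, already 240
  meta0 <- standardizeCeph(matrix(runif(240 * 240), 240, 240))@meta
  expect_equal(unname(unprojectBbox(c(10, 20, 100, 200), meta0)),
               c(10, 20, 100, 200))

  # pure x2 scale
  meta2 <- standardizeCeph(matrix(runif(480 * 480), 480, 480))@meta
  expect_equal(unname(unprojectBbox(c(10, 20, 100, 200), meta2)),
               c(20, 40, 200, 400))

  # round trip on boxes inside the content region (detector-space x range
  # [20, 80] * 240/100 = [48, 192] for the 20-px side pads) is exact
  set.seed(3)
  for (rep in 1:10) {
    box <- sort(runif(2, 49, 191))
    boy <- sort(runif(2, 1, 239))
    det <- c(box[1], boy[1], box[2], boy[2])
    back <- projectBbox(unprojectBbox(det, meta), meta)
    expect_lt(max(abs(back - det)), 1e-9)
  }

  expect_error(unprojectBbox(c(0, 0, 10, 10), list(square_side = 100,
    out_size = 240, pad_left = 20, pad_top = 0, orig_w = 60, orig_h = 100)),
    "outside")
})

test_that("cropResize returns 256x256 and matches a naive bicubic oracle", {
  set.seed(4)
  raw <- matrix(runif(256 * 256), 256, 256)
  out <- cropResize(raw, c(0, 0, 256, 256))
  expect_equal(imagePixels(out), raw)        # full-size box is the identity

  expect_equal(dim(imagePixels(cropResize(raw, c(30.2, 40.7, 200, 180)))),
               c(256, 256))
  expect_error(cropResize(raw, c(10, 10, 10, 40)), "degenerate|empty")

  # independent naive Catmull-Rom implementation on a small half-scale case
  cr <- function(t) {
    at <- abs(t)
    ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
           ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
  }
  naive <- function(m, oh, ow) {
    out <- matrix(0, oh, ow)
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      sy <- (i - 0.5) * nrow(m) / oh - 0.5
      sx <- (j - 0.5) * ncol(m) / ow - 0.5
      acc <- 0
      for (a in -1:2) for (b in -1:2) {
        yy <- min(max(floor(sy) + a, 0), nrow(m) - 1)
        xx <- min(max(floor(sx) + b, 0), ncol(m) - 1)
        acc <- acc + m[yy + 1, xx + 1] *
          cr(sy - (floor(sy) + a)) * cr(sx - (floor(sx) + b))
      }
      out[i, j] <- acc
    }
    out
  }
  small <- matrix(runif(16 * 16), 16, 16)
  expect_equal(resizeBicubic(small, 8, 8, clip = FALSE), naive(small, 8, 8),
               tolerance = 1e-12)
})

test_that("augmentation is seeded, masks the requested fraction, and is the
           identity with zero parameters", {
  img <- grayImage(matrix(runif(128 * 128), 128, 128))
  expect_identical(augmentImage(img, seed = 5), img)

  a1 <- augmentImage(img, noise_sd = 0.05, mask_fraction = 0.25,
                     max_rotation_deg = 8, max_translation_px = 5,
                     zoom_range = 0.1, seed = 77)
  a2 <- augmentImage(img, noise_sd = 0.05, mask_fraction = 0.25,
                     max_rotation_deg = 8, max_translation_px = 5,
                     zoom_range = 0.1, seed = 77)
  expect_identical(imagePixels(a1), imagePixels(a2))
  expect_equal(dim(imagePixels(a1)), dim(imagePixels(img)))
  expect_gte(min(imagePixels(a1)), 0)
  expect_lte(max(imagePixels(a1)), 1)

  # masking a constant-1 image zeroes 25% +/- 2% of the pixels
  ones <- grayImage(matrix(1, 256, 256))
  masked <- augmentImage(ones, mask_fraction = 0.25, seed = 6)
  expect_lt(abs(mean(imagePixels(masked) == 0) - 0.25), 0.02)
})

test_that("histogram equalisation flattens the intensity distribution", {
  set.seed(7)
  skewed <- matrix(rbeta(256 * 256, 5, 1.3), 256, 256)
  eq <- histogramEqualize(skewed)
  # after equalisation the quartiles are near-uniformly spaced
  qs <- quantile(eq, c(0.25, 0.5, 0.75))
  expect_lt(max(abs(qs - c(0.25, 0.5, 0.75))), 0.05)
  expect_identical(histogramEqualize(matrix(0.3, 4, 4)), matrix(0.3, 4, 4))
})
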