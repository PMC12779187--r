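# Fully convolutional autoencoder with spatial attention.
#
# Feature maps are stored as (channels x positions) matrices, positions in
# column-major order over the H x W grid. Convolutions are computed as a sum
# over the k^2 kernel offsets of one dense matrix product each (the gathered
# input columns for that offset against the offset's weight slice), which
# keeps everything inside BLAS and makes forward/backward exactly
# reproducible. Transposed convolutions are the adjoint scatter of the same
# geometry.

# ---- geometry -------------------------------------------------------------

.convGeom <- function(H, W, k, s, p) {
  Hp <- H + 2 * p; Wp <- W + 2 * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  idx <- vector("list", k * k)
  t <- 1L
  for (b in 0:(k - 1)) for (a in 0:(k - 1)) {
    rows <- a + s * (0:(Ho - 1)) + 1L
    cols <- b + s * (0:(Wo - 1)) + 1L
    idx[[t]] <- as.vector(outer(rows, (cols - 1L) * Hp, "+"))
    t <- t + 1L
  }
  content <- as.vector(outer((p + 1):(p + H), ((p + 1):(p + W) - 1L) * Hp, "+"))
  list(H = H, W = W, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, k = k, s = s, p = p,
       idx = idx, content = content)
}

.pad <- function(X, geom) {
  if (geom$p == 0 && geom$Hp == geom$H && geom$Wp == geom$W) return(X)
  Xp <- matrix(0, nrow(X), geom$Hp * geom$Wp)
  Xp[, geom$content] <- X
  Xp
}

.convForward <- function(X, Wl, b, geom) {
  Xp <- .pad(X, geom)
  Y <- matrix(b, length(b), geom$Ho * geom$Wo)
  for (t in seq_along(geom$idx))
    Y <- Y + Wl[[t]] %*% Xp[, geom$idx[[t]], drop = FALSE]
  list(out = Y, Xp = Xp)
}

.convBackward <- function(dY, Xp, Wl, geom) {
  dW <- vector("list", length(Wl))
  dXp <- matrix(0, nrow(Xp), ncol(Xp))
  for (t in seq_along(geom$idx)) {
    cols <- geom$idx[[t]]
    dW[[t]] <- dY %*% t(Xp[, cols, drop = FALSE])
    dXp[, cols] <- dXp[, cols] + t(Wl[[t]]) %*% dY
  }
  list(dX = dXp[, geom$content, drop = FALSE], dW = dW, db = rowSums(dY))
}

# transposed conv: weights are lists of (Cin x Cout) slices over the
# *output-side* geometry (the conv that would map output back to input)
.tconvForward <- function(X, Wl, b, geom) {
  Cout <- ncol(Wl[[1]])
  Yp <- matrix(0, Cout, geom$Hp * geom$Wp)
  for (t in seq_along(geom$idx)) {
    cols <- geom$idx[[t]]
    Yp[, cols] <- Yp[, cols] + t(Wl[[t]]) %*% X
  }
  list(out = Yp[, geom$content, drop = FALSE] + b, X = X)
}

.tconvBackward <- function(dY, X, Wl, geom) {
  dYp <- matrix(0, nrow(dY), geom$Hp * geom$Wp)
  dYp[, geom$content] <- dY
  dX <- matrix(0, nrow(X), ncol(X))
  dW <- vector("list", length(Wl))
  for (t in seq_along(geom$idx)) {
    g <- dYp[, geom$idx[[t]], drop = FALSE]
    dX <- dX + Wl[[t]] %*% g
    dW[[t]] <- X %*% t(g)
  }
  list(dX = dX, dW = dW, db = rowSums(dY))
}

.rowMaxArg <- function(X) {
  # max and argmax over channels (rows) per position
  mx <- X[1, ]; arg <- rep.int(1L, ncol(X))
  C <- nrow(X)
  if (C > 1) for (c in 2:C) {
    upd <- X[c, ] > mx
    if (any(upd)) { mx[upd] <- X[c, upd]; arg[upd] <- c }
  }
  list(max = mx, arg = arg)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Spatial attention: a per-position multiplicative gate in [0, 1] computed by
# a 7x7 convolution over the channel-wise mean and max maps, then a logistic
# squashing; the gate re-weights every channel at that position.
.attnForward <- function(X, layer) {
  mm <- colMeans(X)
  mx <- .rowMaxArg(X)
  Z <- rbind(mm, mx$max)
  cf <- .convForward(Z, layer$W, layer$b, layer$geom)
  A <- .sigmoid(cf$out)                      # 1 x positions
  Y <- X * rep(A, each = nrow(X))
  list(out = Y, cache = list(X = X, Zp = cf$Xp, A = A, arg = mx$arg))
}

.attnBackward <- function(dY, layer, cache) {
  X <- cache$X; A <- cache$A
  C <- nrow(X)
  dX <- dY * rep(A, each = C)
  dA <- colSums(dY * X)
  dLogit <- matrix(dA * A * (1 - A), 1)
  cb <- .convBackward(dLogit, cache$Zp, layer$W, layer$geom)
  dZ <- cb$dX                                # 2 x positions (mean, max)
  dX <- dX + matrix(rep(dZ[1, ] / C, each = C), C)
  dX[cbind(cache$arg, seq_len(ncol(X)))] <-
    dX[cbind(cache$arg, seq_len(ncol(X)))] + dZ[2, ]
  list(dX = dX, dW = cb$dW, db = cb$db)
}

# ---- architecture ---------------------------------------------------------

.initConvW <- function(cin, cout, k, tconv = FALSE) {
  sdv <- sqrt(2 / (cin * k * k))
  lapply(seq_len(k * k), function(i) {
    if (tconv) matrix(rnorm(cin * cout, 0, sdv), cin, cout)
    else matrix(rnorm(cout * cin, 0, sdv), cout, cin)
  })
}

.buildLayers <- function(cfg) {
  sz <- cfg$input_size
  f <- cfg$filters
  lc <- cfg$latent_channels
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  cin <- 1L
  h <- sz
  for (i in seq_along(f)) {
    g <- .convGeom(h, h, 3L, 2L, 1L)
    add(list(type = "conv", name = paste0("enc", i), geom = g,
             W = .initConvW(cin, f[i], 3L), b = numeric(f[i])))
    add(list(type = "relu", name = paste0("relu_enc", i)))
    h <- g$Ho
    if (isTRUE(cfg$attention))
      add(list(type = "attn", name = paste0("attn", i),
               geom = .convGeom(h, h, 7L, 1L, 3L),
               W = .initConvW(2L, 1L, 7L), b = numeric(1)))
    cin <- f[i]
  }
  add(list(type = "conv", name = "latent", geom = .convGeom(h, h, 1L, 1L, 0L),
           W = .initConvW(cin, lc, 1L), b = numeric(lc)))
  add(list(type = "conv", name = "expand", geom = .convGeom(h, h, 1L, 1L, 0L),
           W = .initConvW(lc, cin, 1L), b = numeric(cin)))
  add(list(type = "relu", name = "relu_expand"))
  for (i in rev(seq_along(f))) {
    cout <- if (i == 1) 1L else f[i - 1]
    g <- .convGeom(2L * h, 2L * h, 4L, 2L, 1L)   # adjoint geometry: out -> in
    add(list(type = "tconv", name = paste0("dec", i), geom = g,
             W = .initConvW(f[i], cout, 4L, tconv = TRUE), b = numeric(cout)))
    h <- 2L * h
    if (i > 1) add(list(type = "relu", name = paste0("relu_dec", i)))
  }
  add(list(type = "sigmoid", name = "out"))
  layers
}

.forwardLayers <- function(layers, X, upto = length(layers), cache = FALSE) {
  caches <- if (cache) vector("list", length(layers)) else NULL
  for (i in seq_len(upto)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      cf <- .convForward(X, l$W, l$b, l$geom)
      if (cache) caches[[i]] <- cf$Xp
      X <- cf$out
    } else if (l$type == "tconv") {
      tf <- .tconvForward(X, l$W, l$b, l$geom)
      if (cache) caches[[i]] <- tf$X
      X <- tf$out
    } else if (l$type == "relu") {
      if (cache) caches[[i]] <- X > 0
      X <- pmax(X, 0)
    } else if (l$type == "sigmoid") {
      X <- .sigmoid(X)
      if (cache) caches[[i]] <- X
    } else if (l$type == "attn") {
      af <- .attnForward(X, l)
      if (cache) caches[[i]] <- af$cache
      X <- af$out
    }
  }
  list(out = X, caches = caches)
}

.backwardLayers <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dX <- dOut
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      cb <- .convBackward(dX, caches[[i]], l$W, l$geom)
      grads[[i]] <- list(dW = cb$dW, db = cb$db); dX <- cb$dX
    } else if (l$type == "tconv") {
      tb <- .tconvBackward(dX, caches[[i]], l$W, l$geom)
      grads[[i]] <- list(dW = tb$dW, db = tb$db); dX <- tb$dX
    } else if (l$type == "relu") {
      dX <- dX * caches[[i]]
    } else if (l$type == "sigmoid") {
      s <- caches[[i]]; dX <- dX * s * (1 - s)
    } else if (l$type == "attn") {
      ab <- .attnBackward(dX, l, caches[[i]])
      grads[[i]] <- list(dW = ab$dW, db = ab$db); dX <- ab$dX
    }
  }
  grads
}

# ---- public API -----------------------------------------------------------

#' Build the spatial-attention convolutional autoencoder
#'
#' Encoder: three stride-2 3x3 convolutions with 32, 64 and 128 filters (each
#' followed by ReLU and a spatial-attention gate), then a 1x1 convolution to a
#' 4-channel latent map -- for a 256 x 256 input the feature-map chain is
#' 128x128x32 -> 64x64x64 -> 32x32x128 -> 32x32x4. The decoder mirrors the
#' encoder with stride-2 transposed convolutions back to 256 x 256; there are
#' no fully connected layers anywhere. Weights are He-initialised under
#' `seed`, so identical configs give identical models.
#'
#' @param input_size input side length in pixels; must be divisible by 8
#'   (default 256).
#' @param filters encoder filter counts per stage (default `c(32, 64, 128)`).
#' @param latent_channels latent map channels (default 4).
#' @param attention enable spatial-attention gates (default TRUE).
#' @param epochs,batch_size,lr,seed training defaults stored in the config.
#' @return an untrained [ConvAutoencoder-class].
#' @export
buildAutoencoder <- function(input_size = 256, filters = c(32, 64, 128),
                             latent_channels = 4, attention = TRUE,
                             epochs = 5, batch_size = 8, lr = 1e-3, seed = 1) {
  if (length(filters) != 3) .stopf("invalid architecture: need 3 encoder stages")
  if (input_size %% 8 != 0 || input_size < 8)
    .stopf("invalid architecture: input_size must be divisible by %d", 8)
  cfg <- list(input_size = as.integer(input_size), filters = as.integer(filters),
              latent_channels = as.integer(latent_channels),
              attention = isTRUE(attention), loss = "mse",
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = lr, seed = as.integer(seed))
  layers <- withr::with_seed(cfg$seed, .buildLayers(cfg))
  new("ConvAutoencoder", config = cfg, weights = layers, trained = FALSE,
      lossTrace = numeric())
}

.imageToVec <- function(img, sz) {
  px <- if (is(img, "GrayImage")) img@pixels else as.matrix(img)
  if (nrow(px) != sz || ncol(px) != sz)
    .stopf("image is %dx%d but the model expects %dx%d",
           nrow(px), ncol(px), sz, sz)
  matrix(as.vector(px), 1)
}

.latentIndex <- function(layers) which(vapply(layers, function(l)
  identical(l$name, "latent"), logical(1)))

#' Feature-map shape chain of an autoencoder
#'
#' @param model a [ConvAutoencoder-class].
#' @return list of named `c(height, width, channels)` vectors per stage.
#' @export
aeShapes <- function(model) {
  out <- list()
  for (l in model@weights) {
    if (l$type == "conv")
      out[[l$name]] <- c(height = l$geom$Ho, width = l$geom$Wo,
                         channels = length(l$b))
    if (l$type == "tconv")
      out[[l$name]] <- c(height = l$geom$H, width = l$geom$W,
                         channels = length(l$b))
  }
  out
}

#' Encode an image into the spatial latent map
#'
#' @param model a [ConvAutoencoder-class].
#' @param image a [GrayImage-class] or matrix matching the model input size.
#' @return numeric array `(input_size/8, input_size/8, latent_channels)`.
#' @export
encodeImage <- function(model, image) {
  X <- .imageToVec(image, model@config$input_size)
  li <- .latentIndex(model@weights)
  Z <- .forwardLayers(model@weights, X, upto = li)$out
  h <- model@config$input_size %/% 8L
  C <- nrow(Z)
  arr <- array(0, c(h, h, C))
  for (c in seq_len(C)) arr[, , c] <- matrix(Z[c, ], h, h)
  arr
}

#' Reconstruct an image through the autoencoder
#'
#' @inheritParams encodeImage
#' @return reconstructed pixel matrix in `[0, 1]`.
#' @export
reconstructImage <- function(model, image) {
  X <- .imageToVec(image, model@config$input_size)
  Y <- .forwardLayers(model@weights, X)$out
  matrix(Y, model@config$input_size, model@config$input_size)
}

.datasetLoss <- function(layers, Xs) {
  mean(vapply(Xs, function(X) {
    Y <- .forwardLayers(layers, X)$out
    mean((Y - X)^2)
  }, numeric(1)))
}

#' Train the autoencoder by reconstruction
#'
#' Mean-squared-error reconstruction loss, Adam updates, mini-batches in a
#' seeded shuffled order. The loss trace records the dataset loss before any
#' update (index 1) and after each epoch; training on a non-degenerate
#' dataset drives the final loss below the initial one.
#'
#' @param model a [ConvAutoencoder-class].
#' @param images list of [GrayImage-class] / matrices matching the input size.
#' @param epochs,batch_size,lr overrides of the config defaults.
#' @param seed RNG seed for shuffling (default: config seed).
#' @return trained [ConvAutoencoder-class] with `lossTrace` filled.
#' @export
trainAutoencoder <- function(model, images, epochs = NULL, batch_size = NULL,
                             lr = NULL, seed = NULL) {
  if (length(images) < 1) .stopf("empty training set")
  cfg <- model@config
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  bs <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)
  lr <- if (is.null(lr)) cfg$lr else lr
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  Xs <- lapply(images, .imageToVec, sz = cfg$input_size)
  layers <- model@weights

  # Adam state mirrors each parameterised layer
  opt <- lapply(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = lapply(l$W, function(w) w * 0), vW = lapply(l$W, function(w) w * 0),
         mb = l$b * 0, vb = l$b * 0)
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L

  trace <- .datasetLoss(layers, Xs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(Xs))
      for (start in seq(1, length(ord), by = bs)) {
        batch <- ord[start:min(start + bs - 1, length(ord))]
        acc <- NULL
        for (j in batch) {
          X <- Xs[[j]]
          fw <- .forwardLayers(layers, X, cache = TRUE)
          dOut <- 2 * (fw$out - X) / length(X)
          g <- .backwardLayers(layers, fw$caches, dOut)
          acc <- if (is.null(acc)) g else mapply(function(a, b) {
            if (is.null(a)) return(NULL)
            list(dW = mapply(`+`, a$dW, b$dW, SIMPLIFY = FALSE),
                 db = a$db + b$db)
          }, acc, g, SIMPLIFY = FALSE)
        }
        step <- step + 1L
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        nB <- length(batch)
        for (i in seq_along(layers)) {
          if (is.null(acc[[i]])) next
          o <- opt[[i]]
          for (t in seq_along(layers[[i]]$W)) {
            gW <- acc[[i]]$dW[[t]] / nB
            o$mW[[t]] <- beta1 * o$mW[[t]] + (1 - beta1) * gW
            o$vW[[t]] <- beta2 * o$vW[[t]] + (1 - beta2) * gW^2
            layers[[i]]$W[[t]] <- layers[[i]]$W[[t]] -
              lr * (o$mW[[t]] / bc1) / (sqrt(o$vW[[t]] / bc2) + eps)
          }
          gb <- acc[[i]]$db / nB
          o$mb <- beta1 * o$mb + (1 - beta1) * gb
          o$vb <- beta2 * o$vb + (1 - beta2) * gb^2
          layers[[i]]$b <- layers[[i]]$b - lr * (o$mb / bc1) / (sqrt(o$vb / bc2) + eps)
          opt[[i]] <- o
        }
      }
      trace <- c(trace, .datasetLoss(layers, Xs))
    }
  })
  new("ConvAutoencoder", config = cfg, weights = layers, trained = TRUE,
      lossTrace = trace)
}

#' Extract the 340-value pooled descriptor for a set of images
#'
#' Encodes each image to its latent map and applies spatial pyramid pooling
#' ([spatialPyramidPool()]); deterministic at inference.
#'
#' @param model a (typically trained) [ConvAutoencoder-class].
#' @param images list of images matching the model input size.
#' @param levels pyramid grid sizes (default `c(1, 2, 4, 8)`).
#' @param op pooling operator, `"max"` (default) or `"mean"`.
#' @return matrix n x 340 with columns `ae_0` ... `ae_339`.
#' @export
extractAeFeatures <- function(model, images, levels = c(1, 2, 4, 8),
                              op = c("max", "mean")) {
  op <- match.arg(op)
  rows <- lapply(images, function(img)
    spatialPyramidPool(encodeImage(model, img), levels = levels, op = op))
  out <- do.call(rbind, rows)
  colnames(out) <- paste0("ae_", seq_len(ncol(out)) - 1)
  rownames(out) <- names(images)
  out
}
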