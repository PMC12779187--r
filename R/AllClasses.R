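#' @import methods
#' @importFrom stats prcomp predict rnorm runif sd var pbinom pchisq quantile optimize setNames
#' @importFrom utils combn read.csv write.csv head
NULL

#' ToothArch: per-tooth centroids of one labelled dental arch
#'
#' One maxillary or mandibular arch represented by the 3D centroid of each
#' tooth, keyed by FDI two-digit code (rownames of `centroids`). The standard
#' complement is 14 teeth (second molar to second molar). Units are mm.
#'
#' @slot archId `"maxilla"` or `"mandible"`.
#' @slot centroids numeric matrix, one row per tooth (rownames = FDI codes),
#'   columns x, y, z in mm.
#' @export
setClass("ToothArch",
  representation(archId = "character", centroids = "matrix"))

setValidity("ToothArch", function(object) {
  msgs <- character()
  if (!object@archId %in% c("maxilla", "mandible"))
    msgs <- c(msgs, "archId must be 'maxilla' or 'mandible'")
  cm <- object@centroids
  if (!is.numeric(cm) || ncol(cm) != 3)
    msgs <- c(msgs, "centroids must be a numeric matrix with 3 columns")
  if (is.null(rownames(cm)) && nrow(cm) > 0)
    msgs <- c(msgs, "centroids must have FDI codes as rownames")
  else if (nrow(cm) > 0) {
    codes <- suppressWarnings(as.integer(rownames(cm)))
    if (anyNA(codes)) msgs <- c(msgs, "rownames must be integer FDI codes")
    else {
      if (anyDuplicated(codes)) msgs <- c(msgs, "duplicate FDI codes")
      if (object@archId %in% c("maxilla", "mandible")) {
        bad <- setdiff(codes, .validFdi(object@archId))
        if (length(bad))
          msgs <- c(msgs, paste0("FDI codes not valid for ", object@archId,
                                 ": ", paste(bad, collapse = ", ")))
      }
    }
  }
  if (length(cm) && !all(is.finite(cm))) msgs <- c(msgs, "non-finite centroid")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ToothArch
#'
#' @param archId `"maxilla"` or `"mandible"`.
#' @param centroids numeric matrix (n x 3, mm) with FDI codes as rownames, or
#'   a data.frame with columns `fdi`, `x`, `y`, `z`.
#' @return a [ToothArch-class] object.
#' @examples
#' cm <- matrix(rnorm(42), 14, 3)
#' rownames(cm) <- c(27:21, 11:17)
#' toothArch("maxilla", cm)
#' @export
toothArch <- function(archId, centroids) {
  if (is.data.frame(centroids)) {
    m <- as.matrix(centroids[, c("x", "y", "z")])
    rownames(m) <- as.character(centroids$fdi)
    centroids <- m
  }
  colnames(centroids) <- c("x", "y", "z")
  new("ToothArch", archId = archId, centroids = centroids)
}

setMethod("show", "ToothArch", function(object) {
  cat(sprintf("ToothArch (%s), %d teeth: %s\n", object@archId,
              nrow(object@centroids),
              paste(rownames(object@centroids), collapse = " ")))
})

#' @describeIn ToothArch-class FDI codes present in the arch.
#' @param x a `ToothArch`.
#' @export
archTeeth <- function(x) rownames(x@centroids)

#' @describeIn ToothArch-class centroid matrix (n x 3, mm).
#' @export
archCentroids <- function(x) x@centroids

#' LandmarkSet: ordered 2D cephalometric landmark coordinates
#'
#' The standard configuration carries 29 ordered (x, y) points in pixel
#' coordinates; all points must be finite and pairwise distinct.
#'
#' @slot points numeric matrix n x 2 (columns x, y), rows in landmark order.
#' @export
setClass("LandmarkSet", representation(points = "matrix"))

setValidity("LandmarkSet", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2) return("points must be an n x 2 numeric matrix")
  if (nrow(p) < 2) return("need at least 2 landmarks")
  if (!all(is.finite(p))) return("non-finite landmark coordinate")
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  if (any(d == 0)) {
    ij <- which(d == 0, arr.ind = TRUE)[1, ]
    return(sprintf("coincident landmarks (%d, %d)", min(ij), max(ij)))
  }
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param points n x 2 numeric matrix of (x, y) pixel coordinates, ordered by
#'   landmark index. The standard cephalometric configuration has n = 29.
#' @return a [LandmarkSet-class] object.
#' @export
landmarkSet <- function(points) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y")
  new("LandmarkSet", points = points)
}

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet with %d points (x range %.1f..%.1f, y range %.1f..%.1f)\n",
              nrow(object@points), min(object@points[, 1]), max(object@points[, 1]),
              min(object@points[, 2]), max(object@points[, 2])))
})

#' @describeIn LandmarkSet-class landmark coordinate matrix.
#' @param x a `LandmarkSet`.
#' @export
landmarkPoints <- function(x) x@points

#' GrayImage: grayscale image with intensities in [0, 1]
#'
#' @slot pixels numeric matrix (rows = image rows), all values in `[0, 1]`.
#' @slot meta list of provenance metadata (padding/scale records used to
#'   invert the squaring transform for bounding boxes).
#' @export
setClass("GrayImage", representation(pixels = "matrix", meta = "list"),
         prototype(meta = list()))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(dim(p)) != 2) return("pixels must be a 2D numeric matrix")
  if (nrow(p) < 1 || ncol(p) < 1) return("empty image")
  if (!all(is.finite(p))) return("non-finite pixel")
  if (min(p) < 0 || max(p) > 1) return("pixel intensities must lie in [0, 1]")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities; values outside `[0,1]` are an
#'   error (use [standardizeCeph()] for raw 8-bit input).
#' @param meta optional metadata list.
#' @return a [GrayImage-class].
#' @export
grayImage <- function(pixels, meta = list()) {
  new("GrayImage", pixels = as.matrix(pixels), meta = meta)
}

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %d x %d, intensity range [%.3f, %.3f]\n",
              nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels)))
})

#' @describeIn GrayImage-class pixel matrix.
#' @param x a `GrayImage`.
#' @export
imagePixels <- function(x) x@pixels

#' @describeIn GrayImage-class metadata list.
#' @export
imageMeta <- function(x) x@meta

#' QuadraticBezier: 3-control-point quadratic Bezier curve
#'
#' B(t) = (1-t)^2 p0 + 2 t (1-t) p1 + t^2 p2, t in [0, 1]; by construction
#' B(0) = p0 and B(1) = p2.
#'
#' @slot p0,p1,p2 numeric(3) control points (mm).
#' @export
setClass("QuadraticBezier",
  representation(p0 = "numeric", p1 = "numeric", p2 = "numeric"))

setValidity("QuadraticBezier", function(object) {
  for (s in c("p0", "p1", "p2")) {
    v <- slot(object, s)
    if (length(v) != 3 || !all(is.finite(v)))
      return(sprintf("%s must be a finite numeric(3)", s))
  }
  TRUE
})

#' Construct a QuadraticBezier curve
#' @param p0,p1,p2 numeric(3) control points.
#' @return a [QuadraticBezier-class].
#' @export
quadraticBezier <- function(p0, p1, p2)
  new("QuadraticBezier", p0 = as.numeric(p0), p1 = as.numeric(p1), p2 = as.numeric(p2))

setMethod("show", "QuadraticBezier", function(object) {
  cat("QuadraticBezier\n  p0:", signif(object@p0, 4),
      "\n  p1:", signif(object@p1, 4), "\n  p2:", signif(object@p2, 4), "\n")
})

#' ConfusionMatrix: binary-classification cell counts
#'
#' @slot tp,fp,fn,tn non-negative integer counts (positive class =
#'   extraction).
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer", fn = "integer", tn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (anyNA(v) || any(v < 0)) return("cell counts must be non-negative integers")
  TRUE
})

#' Construct a ConfusionMatrix
#' @param tp,fp,fn,tn cell counts.
#' @return a [ConfusionMatrix-class].
#' @examples confusionMatrix(tp = 24, fn = 14, fp = 15, tn = 71)
#' @export
confusionMatrix <- function(tp, fp, fn, tn)
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (n = %d)\n            pred+  pred-\n  actual+  %5d  %5d\n  actual-  %5d  %5d\n",
              object@tp + object@fp + object@fn + object@tn,
              object@tp, object@fn, object@fp, object@tn))
})

#' ConvAutoencoder: fully convolutional autoencoder with spatial attention
#'
#' Encoder: three stride-2 conv stages (32, 64, 128 filters), each followed by
#' a spatial-attention block, then a 1x1 conv to a 4-channel latent map
#' (32 x 32 x 4 for a 256 x 256 input). Decoder mirrors the encoder with
#' transposed convolutions. See [buildAutoencoder()].
#'
#' @slot config list of architecture/training settings.
#' @slot weights list of layer weight arrays.
#' @slot trained logical flag.
#' @slot lossTrace numeric per-epoch reconstruction loss (index 1 = loss
#'   before any update).
#' @export
setClass("ConvAutoencoder",
  representation(config = "list", weights = "list", trained = "logical",
                 lossTrace = "numeric"),
  prototype(trained = FALSE, lossTrace = numeric()))

setMethod("show", "ConvAutoencoder", function(object) {
  cfg <- object@config
  cat(sprintf("ConvAutoencoder: input %dx%d -> latent %dx%dx%d (%s)\n",
              cfg$input_size, cfg$input_size, cfg$input_size / 8,
              cfg$input_size / 8, cfg$latent_channels,
              if (object@trained) sprintf("trained, final loss %.5f",
                                          utils::tail(object@lossTrace, 1))
              else "untrained"))
})

#' FeatureTable: multi-group feature matrix with binary labels
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose rows are features (with `rowData()$group` in IOS / AE / Land) and
#' whose columns are subjects (with `colData()$label` in 0/1).
#'
#' @export
#' @import SummarizedExperiment
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"group" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must carry a 'group' column")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must carry a 'label' column")
  g <- SummarizedExperiment::rowData(object)$group
  if (!all(g %in% c("IOS", "AE", "Land")))
    return("feature groups must be IOS, AE or Land")
  lab <- SummarizedExperiment::colData(object)$label
  if (!all(lab %in% c(0L, 1L))) return("labels must be 0/1")
  if (anyNA(SummarizedExperiment::assay(object))) return("missing feature values")
  TRUE
})

#' FoldModel: one outer fold's saved preprocessing and tuned classifier
#'
#' @slot fold outer-fold index.
#' @slot trainIds subject ids the fold was fitted on.
#' @slot prep per-group preprocessing (scaler + PCA), fitted on `trainIds`
#'   only.
#' @slot family classifier family name.
#' @slot params tuned hyperparameters.
#' @slot fit fitted classifier object.
#' @slot innerScore best mean inner-fold F1 found by the optimiser.
#' @export
setClass("FoldModel",
  representation(fold = "integer", trainIds = "character", prep = "list",
                 family = "character", params = "list", fit = "ANY",
                 innerScore = "numeric"))

setMethod("show", "FoldModel", function(object) {
  cat(sprintf("FoldModel %d: %s, inner F1 %.3f, %d training subjects\n",
              object@fold, object@family, object@innerScore,
              length(object@trainIds)))
})

#' ExtractionEnsemble: majority-vote ensemble of per-fold models
#'
#' @slot members list of [FoldModel-class] (odd count; one per outer fold).
#' @slot groups feature groups the ensemble consumes.
#' @slot votingRule `"majority"`.
#' @export
setClass("ExtractionEnsemble",
  representation(members = "list", groups = "character", votingRule = "character"),
  prototype(votingRule = "majority"))

setValidity("ExtractionEnsemble", function(object) {
  if (length(object@members) %% 2 == 0)
    return("ensemble must have an odd number of members for binary voting")
  if (!all(vapply(object@members, is, TRUE, class2 = "FoldModel")))
    return("members must be FoldModel objects")
  TRUE
})

setMethod("show", "ExtractionEnsemble", function(object) {
  cat(sprintf("ExtractionEnsemble: %d members, groups {%s}, %s voting\n",
              length(object@members), paste(object@groups, collapse = ", "),
              object@votingRule))
})
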