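# Seeded synthetic cohort generator. Emulates the structure of the study
# inputs -- two-class dental-arch geometries with a planted crowding effect,
# 29-landmark cephalometric configurations with a planted shape effect, and
# procedurally rendered radiograph-like grayscale images -- so that every
# downstream stage is testable without any clinical data. The images are
# deliberately schematic: they exercise the preprocessing and autoencoder
# contracts, not anatomical realism.

#' SynthConfig: parameters of the synthetic cohort generator
#'
#' @slot nSubjects cohort size.
#' @slot extractionFraction proportion of extraction-class subjects in (0,1);
#'   default 0.311, the study's class ratio.
#' @slot archEffect extra off-curve crowding displacement (mm) planted in
#'   extraction-class arches.
#' @slot landmarkEffect systematic landmark shift (px) planted in the
#'   extraction class.
#' @slot noiseSdArch isotropic centroid noise sd (mm).
#' @slot noiseSdLandmark isotropic landmark noise sd (px).
#' @slot imageSize rendered image side (px).
#' @slot seed global seed; fans out to per-subject substreams so identical
#'   configs reproduce bit-identical cohorts.
#' @export
setClass("SynthConfig",
  representation(nSubjects = "integer", extractionFraction = "numeric",
                 archEffect = "numeric", landmarkEffect = "numeric",
                 noiseSdArch = "numeric", noiseSdLandmark = "numeric",
                 imageSize = "integer", seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@nSubjects < 1) return("n_subjects must be positive")
  f <- object@extractionFraction
  if (!(f > 0 && f < 1)) return("extraction_fraction must lie strictly in (0, 1)")
  if (object@archEffect < 0 || object@landmarkEffect < 0 ||
      object@noiseSdArch < 0 || object@noiseSdLandmark < 0)
    return("effect sizes and noise sds must be non-negative")
  if (object@imageSize < 16) return("image_size too small")
  TRUE
})

#' Construct a SynthConfig
#'
#' Defaults are the package's fixed study-emulation conditions: the paper's
#' class ratio, and clinically plausible effect and noise scales (crowding
#' displacements of 1.5 mm against 0.5 mm centroid noise; 5 px landmark
#' shifts against 2 px landmark noise).
#'
#' @param n_subjects cohort size (positive integer).
#' @param extraction_fraction extraction-class proportion in (0, 1).
#' @param arch_effect crowding displacement (mm) in the extraction class.
#' @param landmark_effect landmark shift (px) in the extraction class.
#' @param noise_sd_arch centroid noise sd (mm).
#' @param noise_sd_landmark landmark noise sd (px).
#' @param image_size image side length (px).
#' @param seed integer seed.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(n_subjects, extraction_fraction = 0.311,
                        arch_effect = 1.5, landmark_effect = 5,
                        noise_sd_arch = 0.5, noise_sd_landmark = 2,
                        image_size = 256, seed = 1) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1)
    .stopf("n_subjects must be a positive integer")
  new("SynthConfig", nSubjects = as.integer(n_subjects),
      extractionFraction = extraction_fraction, archEffect = arch_effect,
      landmarkEffect = landmark_effect, noiseSdArch = noise_sd_arch,
      noiseSdLandmark = noise_sd_landmark, imageSize = as.integer(image_size),
      seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0("SynthConfig: n=%d, extraction fraction %.3f, arch effect ",
                     "%.2f mm, landmark effect %.1f px, seed %d\n"),
              object@nSubjects, object@extractionFraction, object@archEffect,
              object@landmarkEffect, object@seed))
})

# mesiodistal tooth widths (mm), second molar -> central incisor
.toothWidths <- list(
  maxilla  = c(9.5, 10.0, 6.5, 7.0, 7.5, 6.5, 8.5),
  mandible = c(10.5, 11.0, 7.0, 7.0, 6.5, 5.5, 5.0))
.archShape <- list(maxilla = c(halfWidth = 27, depth = 42),
                   mandible = c(halfWidth = 25, depth = 39))

# ideal arch: tooth centroids at fixed arc-length fractions of a symmetric
# parabola in the occlusal (XY) plane, plus the in-plane unit normal at each
# tooth (used to push teeth off-curve when planting crowding)
.archTemplate <- function(archId) {
  w <- .archShape[[archId]]["halfWidth"]; dpt <- .archShape[[archId]]["depth"]
  xs <- seq(-w, w, length.out = 2001)
  ys <- dpt * (1 - (xs / w)^2)
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]

  tw <- .toothWidths[[archId]]
  widths <- c(tw, rev(tw))                       # left M2 ... right M2
  centers <- cumsum(widths) - widths / 2
  frac <- centers / sum(widths)

  pos <- vapply(frac * total, function(s) {
    i <- findInterval(s, cum, all.inside = TRUE)
    a <- (s - cum[i]) / max(cum[i + 1] - cum[i], 1e-12)
    c(xs[i] + a * (xs[i + 1] - xs[i]), ys[i] + a * (ys[i + 1] - ys[i]))
  }, numeric(2))
  # in-plane outward normal from the tangent direction
  nrm <- vapply(frac * total, function(s) {
    i <- findInterval(s, cum, all.inside = TRUE)
    tgt <- c(xs[i + 1] - xs[i], ys[i + 1] - ys[i])
    n <- c(-tgt[2], tgt[1]) / sqrt(sum(tgt^2))
    n
  }, numeric(2))
  cm <- cbind(t(pos), 0)
  rownames(cm) <- as.character(.fdiOrder(archId))
  colnames(cm) <- c("x", "y", "z")
  list(centroids = cm, normals = t(nrm))
}

.randomRotation3 <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr(M)
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

.synthArch <- function(archId, label, effect, noiseSd) {
  tpl <- .archTemplate(archId)
  cm <- tpl$centroids
  if (label == 1L && effect > 0) {
    anterior <- which(as.integer(rownames(cm)) %% 10 <= 3)   # incisors+canines
    pick <- anterior[runif(length(anterior)) < 0.5]
    if (length(pick) == 0) pick <- sample(anterior, 2)
    sgn <- sample(c(-1, 1), length(pick), replace = TRUE)
    cm[pick, 1:2] <- cm[pick, 1:2] + tpl$normals[pick, ] * (sgn * effect)
  }
  cm <- cm + matrix(rnorm(length(cm), 0, noiseSd), nrow(cm))
  R <- .randomRotation3()
  shift <- runif(3, -10, 10)
  cm <- sweep(cm %*% t(R), 2, -shift)
  colnames(cm) <- c("x", "y", "z")
  toothArch(archId, cm)
}

# fixed 29-point cephalometric-like template: cranial vault arc (1-12),
# facial profile column (13-20), mandibular border (21-29)
.landmarkTemplate <- function() {
  th <- seq(2.8, 0.2, length.out = 12)
  vault <- cbind(130 + 85 * cos(th), 95 + 70 * sin(th))
  profile <- cbind(seq(208, 190, length.out = 8),
                   seq(120, 196, length.out = 8))
  jaw <- cbind(seq(185, 95, length.out = 9),
               210 - 28 * sin(seq(0, pi, length.out = 9)))
  pts <- rbind(vault, profile, jaw)
  colnames(pts) <- c("x", "y")
  pts
}

.synthLandmarks <- function(label, effect, noiseSd) {
  pts <- .landmarkTemplate()
  if (label == 1L && effect > 0) {
    shiftIdx <- 21:29                      # mandibular border points
    pts[shiftIdx, ] <- pts[shiftIdx, ] +
      matrix(effect * c(0.8, 0.6), length(shiftIdx), 2, byrow = TRUE)
  }
  pts <- pts + matrix(rnorm(length(pts), 0, noiseSd), nrow(pts))
  s <- 1 + runif(1, -0.08, 0.08)
  ang <- runif(1, -5, 5) * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  ctr <- c(128, 128)
  pts <- sweep(sweep(pts, 2, ctr) %*% t(s * R), 2, -(ctr + runif(2, -8, 8)))
  colnames(pts) <- c("x", "y")
  landmarkSet(pts)
}

.distToSegment <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  len2 <- vx^2 + vy^2
  t <- pmin(pmax(((px - a[1]) * vx + (py - a[2]) * vy) / max(len2, 1e-12), 0), 1)
  sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
}

.synthImage <- function(landmarks, size) {
  pts <- landmarks@points * size / 256      # template lives in 256-space
  gx <- matrix(rep(seq_len(size), each = size), size)   # column coord
  gy <- matrix(rep(seq_len(size), times = size), size)  # row coord
  img <- 0.18 + 0.25 * gy / size +
    0.15 * exp(-((gx - 0.45 * size)^2 + (gy - 0.4 * size)^2) / (2 * (0.3 * size)^2))
  px <- as.vector(gx); py <- as.vector(gy)
  sigma <- size / 128
  addCurve <- function(img, idx, amp) {
    for (i in seq_len(length(idx) - 1)) {
      d <- .distToSegment(px, py, pts[idx[i], ], pts[idx[i + 1], ])
      img <- img + amp * matrix(exp(-d^2 / (2 * sigma^2)), nrow(img))
    }
    img
  }
  img <- addCurve(img, 1:12, 0.35)     # cranial vault
  img <- addCurve(img, 13:20, 0.30)    # facial profile
  img <- addCurve(img, 21:29, 0.40)    # mandibular border
  img <- img + matrix(rnorm(length(img), 0, 0.02), nrow(img))
  grayImage(pmin(pmax(img, 0), 1))
}

#' Generate a labelled synthetic cohort
#'
#' Labels are assigned so that exactly `round-half-up(n * fraction)` subjects
#' are extraction class (192 of 617 at the default fraction). Each subject is
#' generated from its own seed substream, so a subject is bit-reproducible
#' given the config seed regardless of which components are requested.
#'
#' @param config a [SynthConfig-class].
#' @param what components to generate: any of `"arches"`, `"landmarks"`,
#'   `"images"` (images require landmarks).
#' @return list of subjects, each a list with `subject_id`, `label`,
#'   `maxilla`, `mandible`, `landmarks`, `image` (NULL when not requested);
#'   the config is attached as attribute `config`.
#' @examples
#' coh <- generateCohort(synthConfig(20, seed = 1), what = "arches")
#' sum(vapply(coh, `[[`, integer(1), "label"))
#' @export
generateCohort <- function(config, what = c("arches", "landmarks", "images")) {
  what <- match.arg(what, c("arches", "landmarks", "images"), several.ok = TRUE)
  validObject(config)
  n <- config@nSubjects
  k <- floor(n * config@extractionFraction + 0.5)   # round half-up
  labels <- integer(n)
  withr::with_seed(config@seed, labels[sample.int(n, k)] <- 1L)

  lapply(seq_len(n), function(i) {
    subj <- list(subject_id = sprintf("S%04d", i), label = labels[i],
                 maxilla = NULL, mandible = NULL, landmarks = NULL, image = NULL)
    if ("arches" %in% what) {
      withr::with_seed(.substreamSeed(config@seed, 4L * i + 1L), {
        subj$maxilla <- .synthArch("maxilla", labels[i], config@archEffect,
                                   config@noiseSdArch)
        subj$mandible <- .synthArch("mandible", labels[i], config@archEffect,
                                    config@noiseSdArch)
      })
    }
    if (any(c("landmarks", "images") %in% what)) {
      withr::with_seed(.substreamSeed(config@seed, 4L * i + 2L),
        subj$landmarks <- .synthLandmarks(labels[i], config@landmarkEffect,
                                          config@noiseSdLandmark))
    }
    if ("images" %in% what) {
      withr::with_seed(.substreamSeed(config@seed, 4L * i + 3L),
        subj$image <- .synthImage(subj$landmarks, config@imageSize))
    }
    subj
  }) -> subjects
  attr(subjects, "config") <- config
  subjects
}

#' Cohort labels
#' @param cohort list from [generateCohort()].
#' @return integer 0/1 vector named by subject id.
#' @export
cohortLabels <- function(cohort) {
  stats::setNames(vapply(cohort, `[[`, integer(1), "label"),
                  vapply(cohort, `[[`, character(1), "subject_id"))
}

#' Intraoral-scan feature matrix for a cohort
#'
#' @param cohort list from [generateCohort()] (arches present).
#' @param tol Bezier distance tolerance (mm).
#' @return n x 64 matrix, rownames = subject ids.
#' @export
cohortIosFeatures <- function(cohort, tol = 1e-4) {
  rows <- lapply(cohort, function(s)
    extractIosFeatures(s$maxilla, s$mandible, tol = tol))
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(cohort, `[[`, character(1), "subject_id")
  out
}

#' Pairwise-angle feature matrix for a cohort
#'
#' @param cohort list from [generateCohort()] (landmarks present).
#' @return n x 406 matrix, rownames = subject ids.
#' @export
cohortLandFeatures <- function(cohort) {
  rows <- lapply(cohort, function(s) pairwiseAngles(s$landmarks))
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(cohort, `[[`, character(1), "subject_id")
  out
}

#' Write a cohort to a directory of plain-text files and PNGs
#'
#' Writes `subjects.csv` (subject_id, label), per-subject
#' `<id>_maxilla.csv` / `<id>_mandible.csv` centroid tables (fdi, x, y, z in
#' mm), `<id>_landmarks.csv` (index, x, y in px) and `<id>_image.png` (8-bit
#' grayscale), matching the reader layout of [readCohort()].
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  utils::write.csv(data.frame(subject_id = ids,
                              label = vapply(cohort, `[[`, integer(1), "label")),
                   file.path(dir, "subjects.csv"), row.names = FALSE)
  for (s in cohort) {
    for (a in c("maxilla", "mandible")) {
      if (is.null(s[[a]])) next
      cm <- s[[a]]@centroids
      utils::write.csv(data.frame(fdi = rownames(cm), x = cm[, 1],
                                  y = cm[, 2], z = cm[, 3]),
                       file.path(dir, sprintf("%s_%s.csv", s$subject_id, a)),
                       row.names = FALSE)
    }
    if (!is.null(s$landmarks)) {
      p <- s$landmarks@points
      utils::write.csv(data.frame(index = seq_len(nrow(p)), x = p[, 1], y = p[, 2]),
                       file.path(dir, sprintf("%s_landmarks.csv", s$subject_id)),
                       row.names = FALSE)
    }
    if (!is.null(s$image))
      png::writePNG(s$image@pixels,
                    file.path(dir, sprintf("%s_image.png", s$subject_id)))
  }
  invisible(dir)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir cohort directory.
#' @return list of subjects in the [generateCohort()] layout.
#' @export
readCohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "subjects.csv"))
  lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$subject_id[i]
    rd <- function(suffix) {
      f <- file.path(dir, paste0(id, "_", suffix))
      if (file.exists(f)) f else NULL
    }
    subj <- list(subject_id = id, label = as.integer(tab$label[i]),
                 maxilla = NULL, mandible = NULL, landmarks = NULL, image = NULL)
    for (a in c("maxilla", "mandible")) {
      f <- rd(paste0(a, ".csv"))
      if (!is.null(f)) subj[[a]] <- toothArch(a, utils::read.csv(f))
    }
    f <- rd("landmarks.csv")
    if (!is.null(f)) {
      lm <- utils::read.csv(f)
      pm <- as.matrix(lm[order(lm$index), c("x", "y")])
      rownames(pm) <- NULL
      subj$landmarks <- landmarkSet(pm)
    }
    f <- rd("image.png")
    if (!is.null(f)) subj$image <- grayImage(png::readPNG(f))
    subj
  })
}
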