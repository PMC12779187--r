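test_that("archCenter is the unweighted centroid mean", {
  one <- toothArch("maxilla", matrix(c(1, 2, 3), 1, 3,
                                     dimnames = list("11", c("x", "y", "z"))))
  expect_equal(unname(archCenter(one)), c(1, 2, 3))

  pair <- toothArch("maxilla", matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE,
                                      dimnames = list(c("11", "21"), NULL)))
  expect_equal(unname(archCenter(pair)), c(0, 0, 0))

  set.seed(42)
  cm <- matrix(rnorm(42), 14, 3)
  rownames(cm) <- archTeeth(makeIdealArch())
  arch <- toothArch("maxilla", cm)
  # brute-force mean by explicit summation
  acc <- c(0, 0, 0)
  for (i in 1:14) acc <- acc + cm[i, ]
  expect_equal(unname(archCenter(arch)), unname(acc / 14))

  expect_error(archCenter(toothArch("maxilla",
    matrix(numeric(0), 0, 3, dimnames = list(NULL, NULL)))), "empty")
})

test_that("normalizeArch maps to the canonical pose and is rigid", {
  arch <- makeIdealArch()
  norm <- normalizeArch(arch)
  expect_equal(norm@centroids, arch@centroids, tolerance = 1e-9)

  set.seed(7)
  for (rep in 1:5) {
    R <- randomRotation(); t <- rnorm(3, 0, 20)
    moved <- rigidTransform(arch, R, t)
    renorm <- normalizeArch(moved)
    expect_equal(renorm@centroids, norm@centroids, tolerance = 1e-8)
  }

  # pairwise distances preserved on a noisy arch
  set.seed(8)
  noisy <- toothArch("maxilla", arch@centroids + matrix(rnorm(42, 0, 0.8), 14))
  dBefore <- as.matrix(dist(noisy@centroids))
  dAfter <- as.matrix(dist(normalizeArch(noisy)@centroids))
  expect_equal(unname(dAfter), unname(dBefore), tolerance = 1e-9)

  # collinear configuration is degenerate
  line <- toothArch("maxilla", {
    cm <- cbind(x = seq(-6.5, 6.5, 1), y = 0, z = 0)
    rownames(cm) <- archTeeth(arch); cm
  })
  expect_error(normalizeArch(line), "collinear")
})

test_that("standard measurements follow their definitions", {
  arch <- makeIdealArch()
  cm <- arch@centroids
  cm["13", ] <- c(17.5, 20, 0); cm["23", ] <- c(-17.5, 20, 0)
  arch2 <- toothArch("maxilla", cm)
  m <- standardMeasurements(arch2)
  expect_equal(unname(m["inter_canine_width"]), 35)

  # all teeth on the molar-to-molar axis: depth 0
  flat <- toothArch("maxilla", {
    cmf <- cbind(x = seq(-26, 26, 4), y = 5, z = 2)
    rownames(cmf) <- archTeeth(arch); cmf
  })
  expect_equal(unname(standardMeasurements(flat)["arch_depth"]), 0)

  # arch length equals an independent piecewise polyline summation
  m0 <- standardMeasurements(arch)
  ord <- archTeeth(arch)                  # helper builds in anatomical order
  manual <- 0
  for (i in 2:14)
    manual <- manual + sqrt(sum((arch@centroids[ord[i], ] -
                                 arch@centroids[ord[i - 1], ])^2))
  expect_equal(unname(m0["arch_length"]), manual)

  # missing tooth is reported by FDI code
  expect_error(standardMeasurements(
    toothArch("maxilla", arch@centroids[rownames(arch@centroids) != "13", ])),
    "13")
})

test_that("the arch Bezier interpolates molars and the incisor midpoint", {
  cm <- rbind("27" = c(-1, 0, 0), "17" = c(1, 0, 0),
              "21" = c(-0.1, 1, 0), "11" = c(0.1, 1, 0))
  colnames(cm) <- c("x", "y", "z")
  arch <- toothArch("maxilla", cm)
  bez <- fitArchBezier(arch)
  expect_equal(bez@p1, c(0, 2, 0))                  # closed form 2M - (p0+p2)/2
  expect_equal(bezierPoint(bez, 0), bez@p0)
  expect_equal(bezierPoint(bez, 1), bez@p2)
  M <- c(0, 1, 0)
  expect_lt(sqrt(sum((bezierPoint(bez, 0.5) - M)^2)), 1e-9)

  # collinear anchors degenerate to the chord
  cmc <- rbind("27" = c(-1, 0, 0), "17" = c(1, 0, 0),
               "21" = c(-0.1, 0, 0), "11" = c(0.1, 0, 0))
  colnames(cmc) <- c("x", "y", "z")
  bez2 <- fitArchBezier(toothArch("maxilla", cmc))
  expect_lt(distanceToBezier(c(0, 0, 0), bez2), 1e-9)
})

test_that("distanceToBezier agrees with independent oracles", {
  set.seed(11)
  for (rep in 1:10) {
    bez <- quadraticBezier(rnorm(3, 0, 10), rnorm(3, 0, 10), rnorm(3, 0, 10))
    # on-curve points are at distance ~0
    t0 <- runif(1)
    expect_lt(distanceToBezier(bezierPoint(bez, t0), bez, tol = 1e-8), 1e-6)
    # random query vs closed-form cubic-root oracle
    q <- rnorm(3, 0, 15)
    expect_equal(distanceToBezier(q, bez, tol = 1e-8),
                 bezierDistanceCubicOracle(q, bez), tolerance = 1e-6)
  }

  # collapsed curve
  q <- c(3, 4, 0)
  degen <- quadraticBezier(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_equal(distanceToBezier(q, degen), 5, tolerance = 1e-9)

  # 1-Lipschitz in the query point
  set.seed(12)
  bez <- quadraticBezier(rnorm(3), rnorm(3), rnorm(3))
  for (rep in 1:5) {
    a <- rnorm(3); b <- a + rnorm(3, 0, 0.1)
    expect_lte(abs(distanceToBezier(a, bez) - distanceToBezier(b, bez)),
               sqrt(sum((a - b)^2)) + 1e-9)
  }

  expect_error(distanceToBezier(c(0, 0, 0), degen, tol = -1), "tol")
})

test_that("the IOS feature vector has fixed layout and locality", {
  mx <- makeIdealArch("maxilla")
  md <- makeIdealArch("mandible", halfWidth = 25, depth = 39)
  f <- extractIosFeatures(mx, md, tol = 1e-6)
  expect_length(f, 64)
  expect_identical(names(f)[1:4],
    c("mx_arch_length", "mx_inter_molar_width", "mx_inter_canine_width",
      "mx_arch_depth"))
  expect_true(all(grepl("^md_", names(f)[33:64])))
  expect_true(all(is.finite(f)) && all(f >= -1e-12))

  # left/right paired features agree on a symmetric arch
  expect_equal(unname(f["mx_ctr_dist_27"]), unname(f["mx_ctr_dist_17"]),
               tolerance = 1e-9)
  expect_equal(unname(f["mx_bez_dist_23"]), unname(f["mx_bez_dist_13"]),
               tolerance = 1e-9)

  # perturbing a maxillary incisor leaves the mandibular block and the
  # width measurements (which do not reference it) unchanged
  cm <- mx@centroids
  cm["11", ] <- cm["11", ] + c(0.5, -0.3, 0.2)
  f2 <- extractIosFeatures(toothArch("maxilla", cm), md, tol = 1e-6)
  expect_equal(f2[33:64], f[33:64])
  expect_equal(f2["mx_inter_canine_width"], f["mx_inter_canine_width"])
  expect_equal(f2["mx_inter_molar_width"], f["mx_inter_molar_width"])
  expect_false(isTRUE(all.equal(f2["mx_arch_depth"], f["mx_arch_depth"])))
})

test_that("all IOS features are invariant to rigid motion", {
  set.seed(21)
  mx <- makeIdealArch("maxilla")
  md <- makeIdealArch("mandible", halfWidth = 25, depth = 39)
  # jitter so the arch is not perfectly symmetric
  mx <- toothArch("maxilla", mx@centroids + matrix(rnorm(42, 0, 0.4), 14))
  md <- toothArch("mandible", md@centroids + matrix(rnorm(42, 0, 0.4), 14))
  base <- extractIosFeatures(mx, md, tol = 1e-6)
  for (rep in 1:4) {
    R <- randomRotation(); t <- rnorm(3, 0, 30)
    moved <- extractIosFeatures(rigidTransform(mx, R, t),
                                rigidTransform(md, R, t), tol = 1e-6)
    expect_equal(moved, base, tolerance = 1e-7)
  }
})

test_that("labelled meshes reduce to area-weighted centroids", {
  # two right triangles with different areas, same label
  mesh <- list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                     c(10, 0, 0), c(12, 0, 0), c(10, 2, 0)),
    faces = rbind(c(1, 2, 3), c(4, 5, 6)),
    labels = c(11L, 11L))
  arch <- archFromMesh(mesh, "maxilla")
  a1 <- 0.5; a2 <- 2
  c1 <- c(1, 1, 0) / 3; c2 <- c(32, 2, 0) / 3
  expect_equal(unname(archCentroids(arch)["11", ]),
               (a1 * c1 + a2 * c2) / (a1 + a2))

  # PLY round-trip of the same mesh
  ply <- file.path(tempdir(), "tooth.ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 6",
               "property float x", "property float y", "property float z",
               "element face 2",
               "property list uchar int vertex_indices",
               "property int label",
               "end_header",
               apply(mesh$vertices, 1, paste, collapse = " "),
               "3 0 1 2 11", "3 3 4 5 11"), ply)
  rt <- readLabeledPly(ply)
  expect_equal(rt$vertices, mesh$vertices)
  expect_equal(rt$faces, mesh$faces, ignore_attr = TRUE)
  expect_equal(rt$labels, mesh$labels)
})
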