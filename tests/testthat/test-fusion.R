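test_that("the stratified split reproduces the documented rounding rules", {
  labels <- rep(c(1L, 0L), c(192, 425))
  sp <- stratifiedSplit(labels, test_fraction = 0.2, seed = 1)
  expect_length(sp$train, 493)
  expect_length(sp$test, 124)
  expect_equal(sum(labels[sp$test]), 38)
  expect_equal(sum(labels[sp$test] == 0), 86)

  # exact proportionality on a small balanced case
  sp2 <- stratifiedSplit(rep(c(1L, 0L), each = 5), 0.2, seed = 2)
  expect_length(sp2$test, 2)
  expect_equal(sum(rep(c(1L, 0L), each = 5)[sp2$test]), 1)

  expect_identical(stratifiedSplit(labels, 0.2, seed = 7),
                   stratifiedSplit(labels, 0.2, seed = 7))
  expect_error(stratifiedSplit(labels, 0), "0, 1")
  expect_error(stratifiedSplit(rep(1L, 10), 0.2), "both classes")
})

test_that("configuration enumeration follows the canonical order", {
  configs <- makeConfigurations()
  expect_length(configs, 7)
  expect_identical(names(configs),
    c("IOS", "AE", "Land", "AE+Land", "IOS+AE", "IOS+Land", "IOS+AE+Land"))
  expect_identical(configs[["IOS+Land"]], c("IOS", "Land"))
  expect_length(makeConfigurations("IOS"), 1)
  expect_length(makeConfigurations(c("IOS", "AE")), 3)   # 2^2 - 1
})

test_that("group preprocessing centres, scales, and retains 95% variance", {
  set.seed(3)
  # rank-1 data: a single component suffices
  u <- rnorm(40); v <- rnorm(6)
  X1 <- u %o% v + 0
  prep1 <- suppressWarnings(fitGroupPreprocess(X1))
  expect_equal(prep1$k, 1)

  # isotropic Gaussian: compare the retained count against an independent
  # eigen-decomposition of the correlation matrix
  X <- matrix(rnorm(200 * 10), 200, 10)
  prep <- fitGroupPreprocess(X)
  ev <- sort(eigen(cor(X), symmetric = TRUE)$values, decreasing = TRUE)
  kOracle <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  expect_equal(prep$k, kOracle)
  expect_gte(prep$k, 9)
  expect_gte(prep$explained, 0.95)

  # centering contract before projection
  Z <- sweep(sweep(X[, prep$keep], 2, prep$center), 2, prep$scale, "/")
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, ncol(Z)))

  # zero-variance features are dropped with a warning
  Xz <- cbind(X, constant = 5)
  expect_warning(prepz <- fitGroupPreprocess(Xz), "zero-variance")
  expect_equal(sum(prepz$keep), 10)
  expect_equal(ncol(applyGroupPreprocess(prepz, Xz)), prepz$k)
})

test_that("oversampling balances training folds without touching held-out ids", {
  y <- rep(c(1L, 0L), c(10, 30))
  set.seed(4)
  idx <- oversampleTrainingFold(y)
  expect_equal(as.integer(table(y[idx])), c(30L, 30L))
  expect_true(all(idx[-(1:40)] %in% which(y == 1)))   # duplicates are minority
  expect_identical(oversampleTrainingFold(rep(c(0L, 1L), 5)), 1:10)

  # audit: duplicated indices never leave the training fold
  train <- 1:40
  expect_true(all(idx %in% train))
})

test_that("the Bayesian optimiser is seeded and beats its own initial design", {
  space <- list(list(name = "x", type = "real", lower = -2, upper = 2),
                list(name = "y", type = "real", lower = -2, upper = 2))
  obj <- function(p) -(p$x - 0.7)^2 - (p$y + 0.3)^2
  r1 <- withr::with_seed(5, bayesOptimize(obj, space, trials = 30))
  r2 <- withr::with_seed(5, bayesOptimize(obj, space, trials = 30))
  expect_identical(r1$best_params, r2$best_params)
  expect_gt(r1$best_value, max(r1$history$value[1:10]) - 1e-12)
  expect_gt(r1$best_value, -0.05)
  expect_equal(nrow(r1$history), 30)

  # mixed spaces decode integers and categories
  space2 <- list(list(name = "n", type = "int", lower = 1, upper = 9),
                 list(name = "k", type = "cat", values = list("a", "b")))
  r3 <- withr::with_seed(6, bayesOptimize(function(p) {
    expect_true(p$n %in% 1:9); expect_true(p$k %in% c("a", "b")); 0
  }, space2, trials = 5, optimizer = "random"))
  expect_equal(nrow(r3$history), 5)
})

test_that("nested CV is leakage-free, deterministic, and learns planted effects", {
  dat <- cachedIosCohort(100, arch_effect = 4, noise_sd_arch = 0.3, seed = 11)
  ft <- featureTable(ios = dat$ios, labels = dat$labels)
  res <- nestedCV(ft, groups = "IOS", family = "svc", trials = 10, seed = 2)
  expect_length(res$outer_f1, 5)
  expect_gt(mean(res$outer_f1), 0.9)

  res2 <- nestedCV(ft, groups = "IOS", family = "svc", trials = 10, seed = 2)
  expect_identical(res$outer_f1, res2$outer_f1)
  expect_identical(lapply(res$folds, function(f) f@params),
                   lapply(res2$folds, function(f) f@params))

  # leakage audit: saved preprocessing statistics equal statistics
  # recomputed from the fold's training ids alone
  X <- featureMatrix(ft, "IOS")
  for (fm in res$folds) {
    Xtr <- X[fm@trainIds, , drop = FALSE]
    prep <- fm@prep$IOS
    expect_equal(prep$center, colMeans(Xtr[, prep$keep, drop = FALSE]))
    expect_equal(prep$scale, apply(Xtr[, prep$keep, drop = FALSE], 2, sd))
    expect_gte(prep$explained, 0.95)
  }

  # ensemble votes: majority of the member predictions
  preds <- ensemblePredict(res$ensemble, ft)
  votes <- vapply(res$ensemble@members, function(fm) {
    Xm <- applyGroupPreprocess(fm@prep$IOS, X)
    orthofusion:::.predictClassifier(fm@fit, Xm)
  }, integer(nrow(X)))
  expect_identical(unname(preds), as.integer(rowSums(votes) > 2.5))
  expect_gt(mean(preds == dat$labels), 0.9)

  # degenerate ensemble of identical members equals its single member
  solo <- new("ExtractionEnsemble", members = res$folds[c(1, 1, 1)],
              groups = "IOS", votingRule = "majority")
  expect_identical(unname(ensemblePredict(solo, ft)), unname(votes[, 1]))

  expect_error(ensemblePredict(res$ensemble,
    featureTable(land = matrix(rnorm(200 * 4), 200), labels = rep(0:1, 100))),
    "missing feature group")
  expect_error(new("ExtractionEnsemble", members = res$folds[1:2],
                   groups = "IOS", votingRule = "majority"), "odd")
})

test_that("all four classifier families solve a linearly separable problem", {
  set.seed(8)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(f1 = y * 3 + rnorm(n, 0, 0.2), f2 = rnorm(n),
             f3 = -y * 2 + rnorm(n, 0, 0.2))
  ft <- featureTable(ios = X, labels = y)
  rank <- selectModelFamily(ft, groups = "IOS", outer = 5, inner = 4,
                            trials = 5, seed = 3, pca = FALSE)
  expect_equal(nrow(rank), 4)
  expect_setequal(rank$family, c("logistic", "svc", "rf", "dt"))
  expect_true(all(is.finite(rank$sd_f1)))
  expect_true(all(rank$mean_f1 > 0.9))
})

test_that("feature tables validate their structure", {
  X <- matrix(rnorm(20), 10, 2)
  ft <- featureTable(ios = X, labels = rep(0:1, 5))
  expect_s4_class(ft, "FeatureTable")
  expect_identical(unique(featureGroups(ft)), "IOS")
  expect_equal(dim(featureMatrix(ft)), c(10, 2))
  expect_error(featureTable(ios = X, labels = rep(0:1, 3)), "labels")
  expect_error(featureTable(labels = 1:2), "at least one")
  expect_error(featureMatrix(ft, "AE"), "no features")
})
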