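#' @importFrom e1071 svm
#' @importFrom randomForest randomForest
#' @importFrom rpart rpart rpart.control
#' @importFrom glmnet glmnet
NULL

# Fusion classification pipeline: stratified splitting, per-group Z-score +
# PCA preprocessing fitted strictly inside training folds, the seven feature
# configurations, nested cross-validation with Bayesian hyperparameter
# tuning on inner-fold F1, minority oversampling inside training folds, and
# the majority-vote ensemble of per-fold models.

#' Stratified train/test split
#'
#' The test set holds `ceiling(n * test_fraction)` subjects; the minority
#' class contributes the floor of its proportional share and the majority
#' class the remainder, which reproduces a 493/124 split with a 38/86 test
#' composition for 617 subjects with 192 positives at fraction 0.2.
#'
#' @param labels 0/1 vector, optionally named by subject id.
#' @param test_fraction held-out proportion in (0, 1) (default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` id (or index) vectors.
#' @export
stratifiedSplit <- function(labels, test_fraction = 0.2, seed = 1) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    .stopf("test_fraction must lie in (0, 1)")
  if (length(unique(labels)) < 2) .stopf("both classes must be present")
  ids <- if (is.null(names(labels))) seq_along(labels) else names(labels)
  n <- length(labels)
  nTest <- ceiling(n * test_fraction)
  tabs <- table(labels)
  minority <- names(tabs)[which.min(tabs)]
  nTestMin <- floor(nTest * min(tabs) / n)
  nTestMaj <- nTest - nTestMin
  withr::with_seed(as.integer(seed), {
    minIds <- sample(ids[labels == minority])
    majIds <- sample(ids[labels != minority])
  })
  test <- c(minIds[seq_len(nTestMin)], majIds[seq_len(nTestMaj)])
  list(train = setdiff(ids, test), test = test)
}

# stratified k-fold assignment: per class, shuffled then dealt round-robin
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      .stopf("stratification error: class %s has %d members for %d folds",
             cl, length(idx), k)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' The seven feature configurations
#'
#' All non-empty subsets of the feature groups: singletons in the given
#' modality order, then larger subsets alphabetically by label, giving the
#' canonical order IOS, AE, Land, AE+Land, IOS+AE, IOS+Land, IOS+AE+Land.
#'
#' @param groups character vector of group names (default the three
#'   modalities).
#' @return named list of group subsets (2^k - 1 configurations).
#' @export
makeConfigurations <- function(groups = c("IOS", "AE", "Land")) {
  out <- as.list(groups)
  for (sz in seq_along(groups)[-1]) {
    subsets <- utils::combn(groups, sz, simplify = FALSE)
    lab <- vapply(subsets, paste, character(1), collapse = "+")
    out <- c(out, subsets[order(lab)])
  }
  names(out) <- vapply(out, paste, character(1), collapse = "+")
  out
}

#' Fit per-group preprocessing: Z-score scaling and PCA
#'
#' Zero-variance features are dropped with a warning; remaining features are
#' centred and scaled to unit variance, then projected onto the smallest
#' number of principal components whose cumulative explained variance is at
#' least `retain`.
#'
#' @param X training block (subjects x features).
#' @param retain cumulative explained-variance threshold (default 0.95).
#' @param pca apply PCA after scaling (default TRUE).
#' @return preprocessing record for [applyGroupPreprocess()], with fields
#'   `keep`, `center`, `scale`, `rotation`, `k`, `explained`.
#' @export
fitGroupPreprocess <- function(X, retain = 0.95, pca = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) .stopf("need >= 2 training subjects")
  v <- apply(X, 2, stats::var)
  keep <- v > 1e-12
  if (!all(keep))
    warning(sprintf("dropping %d zero-variance feature(s)", sum(!keep)))
  if (!any(keep)) .stopf("all features have zero variance")
  X <- X[, keep, drop = FALSE]
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  rot <- NULL; k <- ncol(Z); expl <- NULL
  if (pca) {
    pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2
    cum <- cumsum(ev) / sum(ev)
    k <- which(cum >= retain)[1]
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    expl <- cum[k]
  }
  list(keep = keep, center = ctr, scale = scl, rotation = rot, k = k,
       explained = expl, retain = retain, pca = pca)
}

#' Apply a fitted preprocessing record to a feature block
#'
#' @param prep record from [fitGroupPreprocess()].
#' @param X subjects x features matrix with the original feature layout.
#' @return transformed subjects x components matrix.
#' @export
applyGroupPreprocess <- function(prep, X) {
  X <- as.matrix(X)[, prep$keep, drop = FALSE]
  Z <- sweep(sweep(X, 2, prep$center), 2, prep$scale, "/")
  if (prep$pca) Z %*% prep$rotation else Z
}

#' Oversample the minority class inside a training fold
#'
#' Randomly duplicates minority-class rows (with replacement, in the current
#' RNG stream) until the class counts are equal. Returns row indices so
#' callers can audit that held-out subjects are never duplicated.
#'
#' @param labels 0/1 training labels.
#' @return integer row indices (original rows followed by duplicates).
#' @export
oversampleTrainingFold <- function(labels) {
  tabs <- table(labels)
  if (length(tabs) < 2 || tabs[1] == tabs[2]) return(seq_along(labels))
  minority <- names(tabs)[which.min(tabs)]
  extra <- sample(which(labels == as.integer(minority)),
                  max(tabs) - min(tabs), replace = TRUE)
  c(seq_along(labels), extra)
}

#' F1 score of the positive class
#'
#' @param truth,pred 0/1 vectors.
#' @return `2 tp / (2 tp + fp + fn)`; 0 when the denominator is 0.
#' @export
f1Score <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# ---- classifier families --------------------------------------------------

.familySpace <- function(family) {
  switch(family,
    svc = list(
      list(name = "C", type = "real", lower = 1e-3, upper = 1e3, log = TRUE),
      list(name = "gamma", type = "real", lower = 1e-4, upper = 1e1, log = TRUE),
      list(name = "kernel", type = "cat", values = list("radial", "linear"))),
    logistic = list(
      list(name = "lambda", type = "real", lower = 1e-4, upper = 1e2, log = TRUE)),
    rf = list(
      list(name = "ntree", type = "int", lower = 100, upper = 500),
      list(name = "mtry_frac", type = "real", lower = 0.1, upper = 0.9),
      list(name = "nodesize", type = "int", lower = 1, upper = 10)),
    dt = list(
      list(name = "cp", type = "real", lower = 1e-4, upper = 0.1, log = TRUE),
      list(name = "maxdepth", type = "int", lower = 2, upper = 10),
      list(name = "minsplit", type = "int", lower = 5, upper = 40)),
    .stopf("unknown classifier family '%s'", family))
}

.padCols <- function(X) if (ncol(X) >= 2) X else cbind(X, `.pad` = 0)

.fitClassifier <- function(family, params, X, y) {
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(family,
    svc = e1071::svm(X, yf, type = "C-classification",
                     kernel = params$kernel, cost = params$C,
                     gamma = params$gamma, scale = FALSE),
    logistic = glmnet::glmnet(.padCols(X), yf, family = "binomial",
                              alpha = 0, lambda = params$lambda),
    rf = randomForest::randomForest(
      X, yf, ntree = params$ntree,
      mtry = max(1, min(ncol(X), round(params$mtry_frac * ncol(X)))),
      nodesize = params$nodesize),
    dt = {
      df <- data.frame(X); df$.y <- yf
      rpart::rpart(.y ~ ., df, method = "class",
                   control = rpart::rpart.control(
                     cp = params$cp, maxdepth = params$maxdepth,
                     minsplit = params$minsplit, xval = 0))
    },
    .stopf("unknown classifier family '%s'", family))
  list(family = family, fit = fit, params = params)
}

.predictClassifier <- function(model, X) {
  out <- switch(model$family,
    svc = as.integer(as.character(predict(model$fit, X))),
    logistic = as.integer(predict(model$fit, .padCols(X),
                                  type = "response")[, 1] > 0.5),
    rf = as.integer(as.character(predict(model$fit, X))),
    dt = as.integer(as.character(predict(model$fit, data.frame(X),
                                         type = "class"))))
  out
}

# fit per-group preprocessing on a training index set and transform any
# index set with it
.prepAndTransform <- function(ft, groups, trainIdx, pca, retain) {
  prep <- list()
  for (g in groups) {
    Xg <- featureMatrix(ft, g)
    prep[[g]] <- suppressWarnings(
      fitGroupPreprocess(Xg[trainIdx, , drop = FALSE],
                         retain = retain, pca = if (is.logical(pca)) pca
                                                else isTRUE(pca[[g]])))
  }
  prep
}

.transformWith <- function(prep, ft, idx) {
  do.call(cbind, lapply(names(prep), function(g)
    applyGroupPreprocess(prep[[g]], featureMatrix(ft, g)[idx, , drop = FALSE])))
}

# ---- nested cross-validation ----------------------------------------------

#' Nested cross-validated model tuning and the per-fold ensemble
#'
#' Stratified outer folds estimate generalisation; inside each outer training
#' fold a stratified inner loop scores every hyperparameter proposal by mean
#' inner-fold F1, and a Gaussian-process Bayesian optimiser spends `trials`
#' evaluations on that objective. The best proposal is refit on the full
#' outer training fold (with fold-internal Z-score + PCA preprocessing and
#' minority oversampling) and scored on the outer held-out fold. The five
#' refitted fold models form the majority-vote ensemble.
#'
#' @param ft a [FeatureTable-class].
#' @param groups feature groups to use (a configuration from
#'   [makeConfigurations()]).
#' @param family classifier family: `"svc"`, `"logistic"`, `"rf"` or `"dt"`.
#' @param outer,inner outer/inner fold counts (defaults 5 and 10).
#' @param trials Bayesian-optimisation evaluation budget (default 100).
#' @param seed integer seed controlling folds, optimiser and oversampling.
#' @param oversample balance classes inside training folds (default TRUE).
#' @param pca logical (all groups) or named list per group.
#' @param retain PCA explained-variance threshold (default 0.95).
#' @param optimizer `"gp"` or `"random"` (see [bayesOptimize()]).
#' @return list with `outer_f1` (per-fold F1 on held-out outer folds),
#'   `folds` (list of [FoldModel-class]), `ensemble`
#'   ([ExtractionEnsemble-class]), and the call settings.
#' @export
nestedCV <- function(ft, groups = c("IOS", "AE", "Land"), family = "svc",
                     outer = 5, inner = 10, trials = 100, seed = 1,
                     oversample = TRUE, pca = TRUE, retain = 0.95,
                     optimizer = c("gp", "random")) {
  optimizer <- match.arg(optimizer)
  groups <- match.arg(groups, c("IOS", "AE", "Land"), several.ok = TRUE)
  y <- subjectLabels(ft)
  ids <- colnames(ft)
  space <- .familySpace(family)

  withr::with_seed(as.integer(seed), {
    foldId <- .stratifiedFolds(y, outer)
    outerF1 <- numeric(outer)
    foldModels <- vector("list", outer)

    for (f in seq_len(outer)) {
      trainIdx <- which(foldId != f)
      testIdx <- which(foldId == f)
      yTr <- y[trainIdx]
      innerId <- .stratifiedFolds(yTr, inner)

      objective <- function(params) {
        scores <- vapply(seq_len(inner), function(j) {
          fitIdx <- trainIdx[innerId != j]
          valIdx <- trainIdx[innerId == j]
          prep <- .prepAndTransform(ft, groups, fitIdx, pca, retain)
          Xfit <- .transformWith(prep, ft, fitIdx)
          Xval <- .transformWith(prep, ft, valIdx)
          yFit <- y[fitIdx]
          sel <- if (oversample) oversampleTrainingFold(yFit)
                 else seq_along(yFit)
          m <- .fitClassifier(family, params, Xfit[sel, , drop = FALSE], yFit[sel])
          f1Score(y[valIdx], .predictClassifier(m, Xval))
        }, numeric(1))
        mean(scores)
      }
      opt <- bayesOptimize(objective, space, trials = trials,
                           optimizer = optimizer)

      prep <- .prepAndTransform(ft, groups, trainIdx, pca, retain)
      Xtr <- .transformWith(prep, ft, trainIdx)
      sel <- if (oversample) oversampleTrainingFold(yTr) else seq_along(yTr)
      m <- .fitClassifier(family, opt$best_params,
                          Xtr[sel, , drop = FALSE], yTr[sel])
      Xte <- .transformWith(prep, ft, testIdx)
      outerF1[f] <- f1Score(y[testIdx], .predictClassifier(m, Xte))

      foldModels[[f]] <- new("FoldModel", fold = f,
                             trainIds = ids[trainIdx], prep = prep,
                             family = family, params = opt$best_params,
                             fit = m, innerScore = opt$best_value)
    }
  })
  ensemble <- new("ExtractionEnsemble", members = foldModels,
                  groups = groups, votingRule = "majority")
  list(outer_f1 = outerF1, folds = foldModels, ensemble = ensemble,
       family = family, groups = groups, seed = as.integer(seed),
       trials = trials, outer = outer, inner = inner)
}

#' Rank classifier families by nested-CV outer F1
#'
#' Runs [nestedCV()] once per family under the same seed (identical outer
#' folds) and ranks families by mean outer-fold F1.
#'
#' @inheritParams nestedCV
#' @param families families to compare (default all four).
#' @return data.frame with `family`, `mean_f1`, `sd_f1`, sorted best first;
#'   the full per-family results are attached as attribute `results`.
#' @export
selectModelFamily <- function(ft, groups = c("IOS", "AE", "Land"),
                              families = c("logistic", "svc", "rf", "dt"),
                              outer = 5, inner = 10, trials = 100, seed = 1,
                              ...) {
  results <- lapply(families, function(fam)
    nestedCV(ft, groups = groups, family = fam, outer = outer, inner = inner,
             trials = trials, seed = seed, ...))
  names(results) <- families
  tab <- data.frame(
    family = families,
    mean_f1 = vapply(results, function(r) mean(r$outer_f1), numeric(1)),
    sd_f1 = vapply(results, function(r) stats::sd(r$outer_f1), numeric(1)))
  tab <- tab[order(-tab$mean_f1), ]
  rownames(tab) <- NULL
  attr(tab, "results") <- results
  tab
}

#' Majority-vote ensemble prediction
#'
#' Each member applies its own saved fold-internal preprocessing and
#' classifier to the new subjects; the prediction is the majority of the
#' (odd number of) member votes.
#'
#' @param ensemble an [ExtractionEnsemble-class].
#' @param newdata a [FeatureTable-class] carrying every feature group the
#'   ensemble requires (labels in `newdata` are ignored).
#' @return integer 0/1 predictions named by subject id.
#' @export
setGeneric("ensemblePredict", function(ensemble, newdata)
  standardGeneric("ensemblePredict"))

#' @rdname ensemblePredict
setMethod("ensemblePredict", signature("ExtractionEnsemble", "FeatureTable"),
  function(ensemble, newdata) {
    missing <- setdiff(ensemble@groups, unique(featureGroups(newdata)))
    if (length(missing))
      .stopf("missing feature group(s): %s", paste(missing, collapse = ", "))
    votes <- vapply(ensemble@members, function(fm) {
      X <- .transformWith(fm@prep, newdata, seq_len(ncol(newdata)))
      .predictClassifier(fm@fit, X)
    }, integer(ncol(newdata)))
    votes <- matrix(votes, ncol = length(ensemble@members))
    stats::setNames(as.integer(rowSums(votes) * 2 > ncol(votes)),
                    colnames(newdata))
  })
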