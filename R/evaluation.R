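# Diagnostic evaluation: the eight confusion-matrix metrics, an exhaustive
# solver that recovers integer confusion matrices from printed (2 dp,
# half-up rounded) accuracy/sensitivity/specificity values, and McNemar
# paired comparisons of accuracy, sensitivity and specificity.

#' Diagnostic metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall), specificity, PPV (precision), NPV,
#' positive and negative likelihood ratios, and F1. Likelihood ratios with a
#' zero denominator are reported as `Inf`.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named numeric: `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `lr_plus`, `lr_minus`, `f1`.
#' @examples
#' metricsFromCM(confusionMatrix(tp = 24, fn = 14, fp = 15, tn = 71))
#' @export
metricsFromCM <- function(cm) {
  validObject(cm)
  tp <- cm@tp; fp <- cm@fp; fn <- cm@fn; tn <- cm@tn
  n <- tp + fp + fn + tn
  if (n == 0) .stopf("empty confusion matrix")
  rate <- function(num, den) if (den == 0) NaN else num / den
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  c(accuracy = (tp + tn) / n,
    sensitivity = sens,
    specificity = spec,
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    lr_plus = if (!is.nan(spec) && spec == 1) Inf else sens / (1 - spec),
    lr_minus = if (!is.nan(spec) && spec == 0) Inf else (1 - sens) / spec,
    f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}

#' Confusion matrix from per-subject predictions
#'
#' @param truth,pred 0/1 vectors (1 = extraction).
#' @return a [ConfusionMatrix-class].
#' @export
cmFromPredictions <- function(truth, pred) {
  if (length(truth) != length(pred)) .stopf("length mismatch")
  confusionMatrix(tp = sum(truth == 1 & pred == 1),
                  fp = sum(truth == 0 & pred == 1),
                  fn = sum(truth == 1 & pred == 0),
                  tn = sum(truth == 0 & pred == 0))
}

#' Recover integer confusion matrices from printed metrics
#'
#' Exhaustively searches all `tp` in `0..n_pos`, `tn` in `0..n_neg` and
#' returns every matrix whose recomputed accuracy, sensitivity and
#' specificity round (half-up, `digits` dp) to the given printed values;
#' additional printed metrics (`ppv`, `npv`, `f1`) disambiguate when
#' supplied. Used to reconstruct worked examples from published performance
#' tables.
#'
#' @param n_pos,n_neg class sizes.
#' @param accuracy,sensitivity,specificity printed values (2 dp).
#' @param ppv,npv,f1 optional extra printed values to filter on.
#' @param digits printed precision (default 2).
#' @return list of [ConfusionMatrix-class] candidates (length >= 1).
#' @examples
#' solveCMFromMetrics(38, 86, accuracy = 0.77, sensitivity = 0.63,
#'                    specificity = 0.83, ppv = 0.62)
#' @export
solveCMFromMetrics <- function(n_pos, n_neg, accuracy, sensitivity,
                               specificity, ppv = NULL, npv = NULL, f1 = NULL,
                               digits = 2) {
  if (n_pos < 1 || n_neg < 1) .stopf("class sizes must be positive")
  grid <- expand.grid(tp = 0:n_pos, tn = 0:n_neg)
  r <- function(x) roundHalfUp(x, digits)
  ok <- r((grid$tp + grid$tn) / (n_pos + n_neg)) == r(accuracy) &
        r(grid$tp / n_pos) == r(sensitivity) &
        r(grid$tn / n_neg) == r(specificity)
  cand <- grid[ok, , drop = FALSE]
  mats <- lapply(seq_len(nrow(cand)), function(i)
    confusionMatrix(tp = cand$tp[i], fp = n_neg - cand$tn[i],
                    fn = n_pos - cand$tp[i], tn = cand$tn[i]))
  if (!is.null(ppv))
    mats <- Filter(function(m) {
      v <- metricsFromCM(m)["ppv"]; !is.nan(v) && r(v) == r(ppv)
    }, mats)
  if (!is.null(npv))
    mats <- Filter(function(m) {
      v <- metricsFromCM(m)["npv"]; !is.nan(v) && r(v) == r(npv)
    }, mats)
  if (!is.null(f1))
    mats <- Filter(function(m) r(metricsFromCM(m)["f1"]) == r(f1), mats)
  if (length(mats) == 0)
    .stopf("infeasible metrics: no integer confusion matrix matches")
  mats
}

#' McNemar paired comparison of two classifiers
#'
#' Given per-subject correctness indicators of classifiers A and B on the
#' same subjects, counts the discordant pairs `b` (A correct, B wrong) and
#' `c` (A wrong, B correct). For `b + c < exact_threshold` the exact
#' two-sided binomial p-value `min(1, 2 P(X <= min(b, c)))` with
#' `X ~ Bin(b + c, 1/2)` is used; otherwise the continuity-corrected
#' chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df.
#'
#' @param correct_a,correct_b logical vectors, one entry per subject.
#' @param exact_threshold discordant-total threshold below which the exact
#'   test is used (default 25).
#' @param alpha significance level for the direction statement.
#' @param method `"auto"` (default), `"exact"` or `"chisq"`.
#' @return list with `b`, `c`, `p`, `method`, and `direction` (`"A>B"`,
#'   `"A<B"`, or `"A&B"` when not significant at `alpha`).
#' @examples
#' mcnemarPaired(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
mcnemarPaired <- function(correct_a, correct_b, exact_threshold = 25,
                          alpha = 0.05, method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  if (length(correct_a) != length(correct_b)) .stopf("length mismatch")
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  n <- b + cc
  if (n == 0) {
    p <- 1; used <- "exact"
  } else if (method == "exact" || (method == "auto" && n < exact_threshold)) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    used <- "exact"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    used <- "chisq"
  }
  direction <- if (p <= alpha) (if (b > cc) "A>B" else "A<B") else "A&B"
  list(b = b, c = cc, p = p, method = used, direction = direction)
}

.sigStars <- function(p) {
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
}

#' Pairwise McNemar comparisons across a set of models
#'
#' For every model pair, compares accuracy (all subjects), sensitivity
#' (positive-class subjects only) and specificity (negative-class subjects
#' only) with [mcnemarPaired()]; 7 models give 21 rows per criterion.
#' Direction statements use the models' names (`A>B`, `A<B`, `A&B`) and
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param predictions named list of 0/1 prediction vectors over the same
#'   subjects.
#' @param labels 0/1 truth vector.
#' @param exact_threshold passed to [mcnemarPaired()].
#' @return data.frame with columns `criterion`, `model_a`, `model_b`, `b`,
#'   `c`, `p`, `result`, `significance`.
#' @export
compareModels <- function(predictions, labels, exact_threshold = 25) {
  if (is.null(names(predictions)) || anyDuplicated(names(predictions)))
    .stopf("predictions must be a uniquely named list")
  lens <- vapply(predictions, length, integer(1))
  if (any(lens != length(labels)))
    .stopf("all models must predict the same subjects")
  pairs <- utils::combn(names(predictions), 2, simplify = FALSE)
  subsetFor <- list(accuracy = seq_along(labels),
                    sensitivity = which(labels == 1),
                    specificity = which(labels == 0))
  rows <- list()
  for (crit in names(subsetFor)) {
    idx <- subsetFor[[crit]]
    for (pr in pairs) {
      ca <- predictions[[pr[1]]][idx] == labels[idx]
      cb <- predictions[[pr[2]]][idx] == labels[idx]
      mc <- mcnemarPaired(ca, cb, exact_threshold = exact_threshold)
      result <- switch(mc$direction,
                       "A>B" = paste(pr[1], ">", pr[2]),
                       "A<B" = paste(pr[1], "<", pr[2]),
                       paste(pr[1], "&", pr[2]))
      rows[[length(rows) + 1]] <- data.frame(
        criterion = crit, model_a = pr[1], model_b = pr[2],
        b = mc$b, c = mc$c, p = mc$p, result = result,
        significance = .sigStars(mc$p))
    }
  }
  do.call(rbind, rows)
}
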