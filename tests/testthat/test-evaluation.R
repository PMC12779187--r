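test_that("metricsFromCM reproduces the published worked examples", {
  # confusion matrix recovered from the printed IOS+Land row (38/86 test set)
  m <- metricsFromCM(confusionMatrix(tp = 24, fn = 14, fp = 15, tn = 71))
  expect_equal(unname(roundHalfUp(m[c("accuracy", "sensitivity", "specificity",
                                      "ppv", "npv", "lr_plus", "lr_minus",
                                      "f1")])),
               c(0.77, 0.63, 0.83, 0.62, 0.84, 3.62, 0.45, 0.62))

  # the landmark-model row
  m2 <- metricsFromCM(confusionMatrix(tp = 31, fn = 7, fp = 37, tn = 49))
  expect_equal(unname(roundHalfUp(m2[c("accuracy", "sensitivity", "specificity",
                                       "ppv", "npv", "lr_plus", "lr_minus",
                                       "f1")])),
               c(0.65, 0.82, 0.57, 0.46, 0.88, 1.90, 0.32, 0.58))

  # perfect classifier
  p <- metricsFromCM(confusionMatrix(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(unname(p[c("accuracy", "sensitivity", "specificity", "ppv",
                          "npv", "f1")]), rep(1, 6))
  expect_equal(unname(p["lr_minus"]), 0)
  expect_equal(unname(p["lr_plus"]), Inf)

  expect_error(metricsFromCM(confusionMatrix(0, 0, 0, 0)), "empty")
})

test_that("solveCMFromMetrics inverts printed tables", {
  sols <- solveCMFromMetrics(38, 86, accuracy = 0.77, sensitivity = 0.63,
                             specificity = 0.83, ppv = 0.62)
  expect_length(sols, 1)
  expect_equal(c(sols[[1]]@tp, sols[[1]]@tn), c(24L, 71L))

  sols2 <- solveCMFromMetrics(38, 86, accuracy = 0.65, sensitivity = 0.82,
                              specificity = 0.57, ppv = 0.46)
  expect_length(sols2, 1)
  expect_equal(c(sols2[[1]]@tp, sols2[[1]]@tn), c(31L, 49L))

  perfect <- solveCMFromMetrics(10, 10, 1, 1, 1)
  expect_equal(c(perfect[[1]]@tp, perfect[[1]]@tn), c(10L, 10L))

  expect_error(solveCMFromMetrics(10, 10, accuracy = 0.2, sensitivity = 1,
                                  specificity = 1), "infeasible")

  # solve o metrics recovers arbitrary matrices when all metrics are used
  set.seed(1)
  for (rep in 1:5) {
    cm <- confusionMatrix(tp = sample(0:30, 1), fp = sample(0:30, 1),
                          fn = sample(0:30, 1), tn = sample(1:30, 1))
    mm <- metricsFromCM(cm)
    if (!all(is.finite(mm[c("ppv", "npv")]))) next
    got <- solveCMFromMetrics(cm@tp + cm@fn, cm@fp + cm@tn,
                              mm["accuracy"], mm["sensitivity"],
                              mm["specificity"], ppv = mm["ppv"],
                              npv = mm["npv"], f1 = mm["f1"])
    hit <- any(vapply(got, function(g)
      g@tp == cm@tp && g@tn == cm@tn, logical(1)))
    expect_true(hit)
  }
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(2)
  for (rep in 1:10) {
    cm <- confusionMatrix(tp = sample(1:30, 1), fp = sample(0:30, 1),
                          fn = sample(0:30, 1), tn = sample(0:30, 1))
    m <- metricsFromCM(cm)
    expect_equal(unname(m["f1"]),
                 2 / (1 / m[["ppv"]] + 1 / m[["sensitivity"]]))
  }
})

test_that("the exact McNemar p matches the binomial-sum oracle", {
  # no discordance
  eq <- mcnemarPaired(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(eq$p, 1)
  expect_identical(eq$direction, "A&B")

  # b = 10, c = 2: p = 2 * sum_{k<=2} C(12, k) / 2^12
  a <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 5))
  b <- c(rep(FALSE, 10), rep(TRUE, 2), rep(TRUE, 5))
  mc <- mcnemarPaired(a, b)
  oracle <- 2 * sum(choose(12, 0:2)) / 2^12
  expect_equal(mc$p, oracle)
  expect_equal(oracle, 158 / 4096)
  expect_identical(mc$method, "exact")
  expect_identical(mc$direction, "A>B")

  # swapping A and B flips the direction, p unchanged
  mc2 <- mcnemarPaired(b, a)
  expect_equal(mc2$p, mc$p)
  expect_identical(mc2$direction, "A<B")

  # random paired vectors: exact branch vs an independent binomial-sum
  set.seed(3)
  for (rep in 1:10) {
    ca <- runif(40) < 0.7; cb <- runif(40) < 0.6
    got <- mcnemarPaired(ca, cb, exact_threshold = 1e9)
    bb <- sum(ca & !cb); cc <- sum(!ca & cb)
    n <- bb + cc
    expect_equal(got$p,
                 if (n == 0) 1 else min(1, 2 * sum(choose(n, 0:min(bb, cc))) / 2^n))
  }
})

test_that("the large-sample branch matches the continuity-corrected chi-square", {
  set.seed(4)
  ca <- runif(400) < 0.75; cb <- runif(400) < 0.65
  got <- mcnemarPaired(ca, cb)
  expect_identical(got$method, "chisq")
  # independent implementation: stats::mcnemar.test on the discordant table
  tab <- table(factor(ca, c(FALSE, TRUE)), factor(cb, c(FALSE, TRUE)))
  expect_equal(got$p, stats::mcnemar.test(tab, correct = TRUE)$p.value)
})

test_that("compareModels emits 21 rows per criterion for 7 models", {
  set.seed(5)
  labels <- rep(c(1L, 0L), c(38, 86))
  preds <- lapply(1:7, function(i) as.integer(runif(124) < 0.4))
  names(preds) <- c("IOS", "AE", "Land", "AE+Land", "IOS+AE", "IOS+Land",
                    "IOS+AE+Land")
  tab <- compareModels(preds, labels)
  expect_equal(nrow(tab), 3 * choose(7, 2))
  expect_setequal(unique(tab$criterion),
                  c("accuracy", "sensitivity", "specificity"))
  expect_equal(sum(tab$criterion == "accuracy"), 21)

  # a model compared with itself is p = 1 everywhere
  same <- compareModels(list(m1 = preds[[1]], m2 = preds[[1]]), labels)
  expect_true(all(same$p == 1))
  expect_true(all(grepl("&", same$result)))

  # constructed discordance counts match the mcnemar oracle per criterion
  posIdx <- which(labels == 1)
  ca <- preds$IOS[posIdx] == 1; cb <- preds$AE[posIdx] == 1
  mc <- mcnemarPaired(ca, cb)
  row <- tab[tab$criterion == "sensitivity" & tab$model_a == "IOS" &
             tab$model_b == "AE", ]
  expect_equal(row$p, mc$p)
  expect_equal(c(row$b, row$c), c(mc$b, mc$c))

  expect_error(compareModels(list(a = 1:3, b = 1:4), rep(0:1, 2)), "same")
})

test_that("predictions round-trip into confusion matrices", {
  truth <- c(1, 1, 0, 0, 1, 0)
  pred <- c(1, 0, 0, 1, 1, 0)
  cm <- cmFromPredictions(truth, pred)
  expect_equal(c(cm@tp, cm@fp, cm@fn, cm@tn), c(2L, 1L, 1L, 2L))
  expect_error(cmFromPredictions(1:3, 1:4), "mismatch")
})
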