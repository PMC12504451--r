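test_that("confusion counts treat afib as the positive class", {
  expect_equal(confusionCounts(c("afib", "norm"), c("afib", "norm")),
               c(TP = 1L, FN = 0L, TN = 1L, FP = 0L))
  expect_equal(confusionCounts(rep("afib", 4),
                               c(rep("afib", 3), "norm"))[c("TP", "FN")],
               c(TP = 3L, FN = 1L))
  set.seed(71)
  truth <- sample(c("norm", "afib"), 100, replace = TRUE)
  pred <- sample(c("norm", "afib"), 100, replace = TRUE)
  cm <- confusionCounts(truth, pred)
  # brute-force pairwise count
  want <- c(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
  for (i in seq_along(truth)) {
    key <- if (truth[i] == "afib" && pred[i] == "afib") "TP"
           else if (truth[i] == "afib") "FN"
           else if (pred[i] == "norm") "TN" else "FP"
    want[key] <- want[key] + 1L
  }
  expect_equal(cm, want)
  expect_equal(sum(cm), 100L)
  expect_error(confusionCounts(c("afib"), c("afib", "norm")),
               class = "slecg_argument_error")
})

test_that("sensitivity and specificity follow their closed forms", {
  ss <- sensitivitySpecificity(c(TP = 3, FN = 1, TN = 10, FP = 0))
  expect_equal(ss[["sensitivity"]], 0.75)
  expect_equal(ss[["specificity"]], 1.0)
  # undefined ratios are flagged, not zeroed
  und <- sensitivitySpecificity(c(TP = 0, FN = 0, TN = 5, FP = 5))
  expect_true(is.na(und[["sensitivity"]]))
  expect_equal(und[["specificity"]], 0.5)
})

test_that("trapezoidal AUROC matches its boundary cases and frozen example", {
  expect_equal(aurocTrapezoid(c(0.9, 0.8, 0.2, 0.1),
                              c("afib", "afib", "norm", "norm")), 1.0)
  expect_equal(aurocTrapezoid(rep(0.5, 6), rep(c("afib", "norm"), 3)), 0.5)
  # 3 of 4 pairs correctly ordered
  expect_equal(aurocTrapezoid(c(0.1, 0.4, 0.35, 0.8),
                              c("norm", "norm", "afib", "afib")), 0.75)
  expect_error(aurocTrapezoid(c(0.1, 0.2), c("afib", "afib")),
               class = "slecg_argument_error")
})

test_that("trapezoidal AUROC equals the pairwise Mann-Whitney oracle", {
  set.seed(72)
  for (case in 1:1000) {
    n <- sample(4:50, 1)
    truth <- sample(c("norm", "afib"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("norm", "afib")
    scores <- round(runif(n), sample(c(1, 2, 6), 1))   # induce ties sometimes
    pos <- scores[truth == "afib"]
    neg <- scores[truth == "norm"]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(aurocTrapezoid(scores, truth), mean(cmp),
                 tolerance = 1e-12)
  }
})

test_that("AUROC complement symmetry holds without ties", {
  set.seed(73)
  truth <- sample(c("norm", "afib"), 30, replace = TRUE)
  truth[1:2] <- c("norm", "afib")
  scores <- runif(30)
  expect_equal(aurocTrapezoid(scores, truth) + aurocTrapezoid(-scores, truth),
               1, tolerance = 1e-12)
})

test_that("trapezoidal AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(74)
  for (case in 1:20) {
    truth <- sample(c("norm", "afib"), 40, replace = TRUE)
    truth[1:2] <- c("norm", "afib")
    scores <- round(runif(40), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(truth, levels = c("norm", "afib")),
      predictor = scores, quiet = TRUE, direction = "<")))
    expect_equal(aurocTrapezoid(scores, truth), ref, tolerance = 1e-10)
  }
})

test_that("the evaluation report assembles all metrics coherently", {
  truth <- c("afib", "afib", "norm", "norm", "afib")
  pred  <- c("afib", "norm", "norm", "afib", "afib")
  # pipeline-oriented scores: high = normal
  scores <- c(0.1, 0.6, 0.9, 0.4, 0.2)
  ev <- evaluatePredictions(truth, pred, scores)
  expect_equal(ev$accuracy, 3 / 5)
  expect_equal(ev$sensitivity, 2 / 3)
  expect_equal(ev$specificity, 1 / 2)
  expect_equal(ev$auroc, aurocTrapezoid(-scores, truth))
})
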