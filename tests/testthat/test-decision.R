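test_that("voting follows the confidence-sum rule on the canonical cases", {
  expect_equal(voteLabels(c("norm", "norm", "afib"), c(0.9, 0.8, 0.7))$label,
               "norm")                                  # 1.7 > 0.7
  # a confident minority segment wins
  v <- voteLabels(c("afib", "norm", "norm"), c(0.99, 0.40, 0.50))
  expect_equal(v$label, "afib")                         # 0.99 > 0.90
  expect_equal(unname(v$class_sums), c(0.90, 0.99))
  expect_equal(voteLabels(rep("norm", 3), c(0.2, 0.2, 0.2))$label, "norm")
  # exact tie goes to afib (screening sensitivity)
  expect_equal(voteLabels(c("norm", "afib"), c(0.5, 0.5))$label, "afib")
  expect_error(voteLabels(character(), numeric()),
               class = "slecg_argument_error")
  expect_error(voteLabels(c("norm", "afib"), 0.5),
               class = "slecg_argument_error")
})

test_that("voting matches a brute-force oracle over seeded random cases", {
  set.seed(61)
  classes <- c("norm", "afib")
  for (case in 1:1200) {
    k <- sample(2:5, 1)
    labels <- sample(classes, k, replace = TRUE)
    conf <- round(runif(k), 3)
    # independent oracle: explicit accumulation loop
    s <- c(norm = 0, afib = 0)
    for (j in seq_len(k)) s[labels[j]] <- s[labels[j]] + conf[j]
    want <- if (s["afib"] >= s["norm"]) "afib" else "norm"
    got <- voteLabels(labels, conf)
    expect_identical(got$label, want)
    expect_equal(unname(got$class_sums), unname(s))
    # permutation invariance
    p <- sample(k)
    expect_identical(voteLabels(labels[p], conf[p])$label, want)
  }
})

test_that("raising an afib segment's confidence never flips the vote away from afib", {
  set.seed(62)
  for (case in 1:200) {
    labels <- sample(c("norm", "afib"), 3, replace = TRUE)
    if (!any(labels == "afib")) labels[1] <- "afib"
    conf <- runif(3)
    i <- which(labels == "afib")[1]
    before <- voteLabels(labels, conf)$label
    conf2 <- conf
    conf2[i] <- min(1, conf[i] + runif(1, 0, 1 - conf[i]))
    after <- voteLabels(labels, conf2)$label
    if (before == "afib") expect_identical(after, "afib")
  }
})

test_that("threshold sweep finds the most accurate boundary with centered tie-breaks", {
  grid <- seq(0.05, 0.95, by = 0.05)
  sw <- sweepThreshold(c(0.9, 0.6, 0.55, 0.1),
                       c("norm", "norm", "afib", "afib"), grid)
  expect_equal(sw$best_threshold, 0.60)
  expect_equal(sw$best_accuracy, 1.0)
  # brute-force recomputation of the whole table (on the same rounded
  # grid the sweep evaluates)
  acc <- vapply(round(grid, 10), function(t)
    mean(ifelse(c(0.9, 0.6, 0.55, 0.1) >= t, "norm", "afib") ==
           c("norm", "norm", "afib", "afib")), numeric(1))
  expect_equal(sw$table$accuracy, acc)
  # perfectly separated around 0.5
  sw2 <- sweepThreshold(c(0.8, 0.7, 0.3, 0.2),
                        c("norm", "norm", "afib", "afib"), grid)
  expect_equal(sw2$best_threshold, 0.50)
  # all-identical scores: full tie, resolved to 0.50
  sw3 <- sweepThreshold(rep(0.4, 6), rep(c("norm", "afib"), 3), grid)
  expect_equal(sw3$best_threshold, 0.50)
  expect_error(sweepThreshold(numeric(), character()),
               class = "slecg_argument_error")
  expect_error(sweepThreshold(0.5, "norm", numeric()),
               class = "slecg_argument_error")
})

test_that("per-sample prediction vote matches manual aggregation of its segments", {
  model <- shared_trained_model()
  fx <- synthRecord(synthConfig("norm", duration_s = 30, fs = 100,
                                heart_rate_bpm = 70, seed = 63))
  sig <- harmonizeSignal(signals(fx$record)[[1]])
  res <- predictSample(model, sig, record_id = "manual")
  expect_s4_class(res, "PredictionResult")
  expect_length(segmentScores(res), 3L)
  labels <- ifelse(segmentScores(res) >= 0.5, "norm", "afib")
  conf <- ifelse(labels == "norm", segmentScores(res), 1 - segmentScores(res))
  expect_identical(finalLabel(res), voteLabels(labels, conf)$label)
  expect_equal(sum(classSums(res)), sum(conf))
  # single-segment record: the vote is that segment's label
  one <- predictSample(model, harmonizeSignal(
    signals(synthRecord(synthConfig("afib", duration_s = 10, fs = 100,
                                    seed = 64))$record)[[1]]))
  expect_length(segmentScores(one), 1L)
  expect_identical(finalLabel(one), segmentLabels(one)[1])
  expect_error(predictSample(model, Signal(rep(0.1, 100), fs = 100)),
               class = "slecg_argument_error")
})
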