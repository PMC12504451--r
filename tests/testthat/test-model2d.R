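test_that("the default architecture reports the expected parameter counts", {
  rep <- countParameters(buildModel(modelConfig()))
  expect_identical(unname(rep$per_layer[c("conv1", "conv2", "conv3",
                                          "conv4", "dense")]),
                   c(320L, 6208L, 24704L, 49280L, 295008L))
  expect_identical(rep$core_total, 375520L)
  expect_identical(rep$grand_total, 375617L)
  # flatten size implied by the pooling schedule: 4 x 6 x 128
  expect_identical(attr(slecg:::.layer_shapes(modelConfig()), "flat"), 3072L)
})

test_that("parameter identities hold for arbitrary valid configurations", {
  cfg <- modelConfig(input_shape = c(64L, 64L, 1L),
                     conv_filters = c(8L, 16L),
                     conv_kernels = list(c(5L, 5L), c(3L, 3L)),
                     pool_sizes = list(c(2L, 2L), c(2L, 2L)),
                     dense_units = 10L, dropout = c(0.25, 0.3, 0.4))
  rep <- countParameters(buildModel(cfg))
  expect_identical(unname(rep$per_layer[["conv1"]]), (5L * 5L * 1L + 1L) * 8L)
  expect_identical(unname(rep$per_layer[["conv2"]]), (3L * 3L * 8L + 1L) * 16L)
  flat <- 16L * 16L * 16L
  expect_identical(unname(rep$per_layer[["dense"]]), (flat + 1L) * 10L)
  expect_identical(unname(rep$per_layer[["output"]]), 11L)
})

test_that("odd input sizes follow the documented floor-division shapes", {
  cfg <- modelConfig(input_shape = c(95L, 95L, 1L))
  shapes <- slecg:::.layer_shapes(cfg)
  # 95 -> 47 -> 23 -> 11 -> (11/3, 11/2) = 3 x 5
  expect_identical(attr(shapes, "flat"), 3L * 5L * 128L)
  m <- buildModel(cfg)
  expect_identical(unname(countParameters(m)$per_layer[["dense"]]),
                   (3L * 5L * 128L + 1L) * 96L)
})

test_that("invalid model configurations are rejected", {
  expect_error(modelConfig(dropout = c(0.1, 0.25, 0.4, 0.5, 0.5)),
               class = "slecg_config_error")
  expect_error(modelConfig(conv_kernels = list(c(3L, 3L))),
               class = "slecg_config_error")
  expect_error(buildModel(modelConfig(pool_sizes = list(c(50L, 50L), c(2L, 2L),
                                                        c(2L, 2L), c(2L, 2L)))),
               class = "slecg_config_error")
})

test_that("training on separable synthetic images reaches high validation accuracy", {
  model <- shared_trained_model()
  hist <- trainingHistory(model)
  expect_gte(nrow(hist), 15L)
  # monotone improvement on the separable set
  expect_lt(hist$loss[15], hist$loss[1])
  expect_lt(hist$loss[nrow(hist)], hist$loss[1])
  expect_gte(hist$val_accuracy[nrow(hist)], 0.95)
  # training-set normal exemplars score above the default boundary
  tr <- shared_train_images()
  norm_scores <- predictSegment(model, tr$images[tr$labels == "norm"])
  expect_gte(mean(norm_scores >= 0.5), 0.95)
})

test_that("training reproduces its history under a fixed seed", {
  tr <- shared_train_images()
  idx <- c(1:24, 201:224)          # small balanced subset
  cfg <- modelConfig(epochs = 2L)
  m1 <- trainModel(buildModel(cfg), tr$images[idx], tr$labels[idx])
  m2 <- trainModel(buildModel(cfg), tr$images[idx], tr$labels[idx])
  expect_equal(trainingHistory(m1), trainingHistory(m2))
  expect_equal(m1@weights, m2@weights)
})

test_that("training input validation catches degenerate calls", {
  tr <- shared_train_images()
  some <- tr$images[1:8]
  m <- buildModel(modelConfig())
  expect_error(trainModel(m, some, rep("afib", 8)),
               class = "slecg_validation_error")
  bad <- array(0, dim = c(64, 64, 4))
  expect_error(trainModel(m, bad, c("afib", "norm", "afib", "norm")),
               class = "slecg_argument_error")
  m0 <- trainModel(m, some, c(rep("afib", 4), rep("norm", 4)), epochs = 0)
  expect_false(m0@trained)
  expect_identical(nrow(trainingHistory(m0)), 0L)
})

test_that("inference is deterministic with dropout disabled and scores lie in [0,1]", {
  model <- shared_trained_model()
  tr <- shared_train_images()
  imgs <- tr$images[c(1, 2, 201, 202)]
  s1 <- predictSegment(model, imgs)
  s2 <- predictSegment(model, imgs)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # batch scoring preserves order
  expect_equal(s1[3], predictSegment(model, imgs[[3]]))
  expect_error(predictSegment(model, array(0, dim = c(64, 64, 1))),
               class = "slecg_argument_error")
})

test_that("model checkpoints round-trip through save/load", {
  model <- shared_trained_model()
  p <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, p)
  back <- loadModel(p)
  tr <- shared_train_images()
  expect_identical(predictSegment(back, tr$images[[1]]),
                   predictSegment(model, tr$images[[1]]))
  expect_error(loadModel(tempfile()), class = "slecg_config_error")
})
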