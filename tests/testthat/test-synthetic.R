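test_that("generated records satisfy length/rate arithmetic and determinism", {
  out <- synthRecord(synthConfig("norm", duration_s = 10, fs = 100,
                                 heart_rate_bpm = 75, seed = 81))
  expect_length(samples(signals(out$record)[[1]]), 1000L)
  expect_lte(abs(length(out$truth$beat_times) - 10 * 75 / 60), 1)
  again <- synthRecord(synthConfig("norm", duration_s = 10, fs = 100,
                                   heart_rate_bpm = 75, seed = 81))
  expect_identical(samples(signals(again$record)[[1]]),
                   samples(signals(out$record)[[1]]))
  expect_identical(again$truth$beat_times, out$truth$beat_times)
})

test_that("rhythm classes differ in RR variability as constructed", {
  af <- synthRecord(synthConfig("afib", duration_s = 60, fs = 100, seed = 82))
  nm <- synthRecord(synthConfig("norm", duration_s = 60, fs = 100, seed = 82))
  cv <- function(x) sd(x) / mean(x)
  expect_gte(cv(af$truth$rr_intervals), 0.2)
  expect_lt(cv(nm$truth$rr_intervals), 0.06)
  # rr_intervals are successive differences of beat_times
  expect_equal(af$truth$rr_intervals, diff(af$truth$beat_times))
})

test_that("noise injection has the stated magnitude and kinds", {
  base <- Signal(rep(0, 3000), fs = 100, lead = "SL")
  expect_identical(samples(addNoise(base, "gaussian", 0)), samples(base))
  pl <- addNoise(base, "powerline", 0.1)
  t <- (0:2999) / 100
  expect_equal(samples(pl), 0.1 * sin(2 * pi * 50 * t), tolerance = 1e-12)
  g <- addNoise(base, "gaussian", 0.3, seed = 9)
  expect_lt(abs(sd(samples(g)) - 0.3) / 0.3, 0.1)
  bl <- addNoise(base, "baseline", 0.2, seed = 9)
  expect_lte(max(abs(samples(bl))), 0.2 + 1e-12)
  expect_error(addNoise(base, "emg", 0.1), class = "slecg_config_error")
})

test_that("polarity and amplitude options act as configured", {
  up <- synthRecord(synthConfig("norm", seed = 83, polarity = "positive"))
  down <- synthRecord(synthConfig("norm", seed = 83, polarity = "negative"))
  expect_equal(samples(signals(down$record)[[1]]),
               -samples(signals(up$record)[[1]]))
  big <- synthRecord(synthConfig("norm", seed = 83, amplitude_scale = 2.5))
  expect_equal(samples(signals(big$record)[[1]]),
               2.5 * samples(signals(up$record)[[1]]))
})

test_that("datasets are balanced, profiled and reproducible", {
  ds <- makeDataset(5, "clinical_100", seed = 84)
  expect_equal(nrow(ds$manifest), 10L)
  expect_equal(sum(ds$manifest$label == "norm"), 5L)
  expect_true(all(ds$manifest$fs == 100 & ds$manifest$duration_s == 10))
  sm <- makeDataset(5, "smart_300", seed = 84)
  expect_true(all(vapply(sm$records, function(r)
    length(samples(signals(r$record)[[1]])), numeric(1)) == 9000))
  again <- makeDataset(5, "smart_300", seed = 84)
  expect_identical(again$manifest, sm$manifest)
  expect_identical(samples(signals(again$records[[3]]$record)[[1]]),
                   samples(signals(sm$records[[3]]$record)[[1]]))
})

test_that("detector ground-truth consistency holds on noiseless output", {
  for (seed in c(85, 86)) {
    fx <- synthRecord(synthConfig("norm", duration_s = 30, fs = 100,
                                  heart_rate_bpm = 80, seed = seed))
    det_t <- (peakIndices(detectRPeaks(signals(fx$record)[[1]])) - 1) / 100
    hits <- vapply(fx$truth$beat_times,
                   function(b) any(abs(det_t - b) <= 0.05), logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synthConfig("flutter"), "arg")
  expect_error(synthConfig(fs = 250), class = "slecg_config_error")
  expect_error(synthConfig(heart_rate_bpm = 20), class = "slecg_config_error")
  expect_error(synthConfig(noise = list(list(kind = "solar", magnitude = 1))),
               class = "slecg_config_error")
})
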