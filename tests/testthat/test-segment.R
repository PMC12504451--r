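test_that("R-peak detector recovers the generator's beat times", {
  for (hr in c(60, 120)) {
    fx <- clean_beat_signal(hr = hr, duration = 10, fs = 100, seed = hr)
    pk <- detectRPeaks(fx$signal)
    truth <- fx$truth$beat_times
    expect_gte(length(peakIndices(pk)), length(truth) - 2L)
    expect_lte(length(peakIndices(pk)), length(truth) + 2L)
    det_t <- (peakIndices(pk) - 1) / 100
    err <- vapply(det_t, function(d) min(abs(truth - d)), numeric(1))
    expect_true(all(err <= 0.05))     # within 50 ms of a true beat
  }
  expect_length(peakIndices(detectRPeaks(Signal(rep(0, 1000), fs = 100))), 0L)
})

test_that("detector sensitivity and PPV stay above 95% across 50-150 bpm", {
  for (hr in c(50, 75, 100, 125, 150)) {
    fx <- clean_beat_signal(hr = hr, duration = 30, fs = 100, seed = 600 + hr)
    det_t <- (peakIndices(detectRPeaks(fx$signal)) - 1) / 100
    truth <- fx$truth$beat_times
    hits <- vapply(truth, function(b) any(abs(det_t - b) <= 0.05), logical(1))
    matched <- vapply(det_t, function(d) any(abs(truth - d) <= 0.05), logical(1))
    expect_gte(mean(hits), 0.95)      # sensitivity
    expect_gte(mean(matched), 0.95)   # positive predictive value
  }
})

test_that("segmentation yields non-overlapping full windows", {
  fx <- clean_beat_signal(hr = 66, duration = 30, fs = 100, seed = 41)
  segs <- segmentSignal(fx$signal, 10)
  expect_length(segments(segs), 3L)
  expect_equal(startIndices(segs), c(1L, 1001L, 2001L))
  expect_true(all(lengths(segments(segs)) == 1000L))
  # exactly one segment when duration equals the window
  one <- segmentSignal(clean_beat_signal(duration = 10, seed = 42)$signal, 10)
  expect_length(segments(one), 1L)
  expect_error(segmentSignal(clean_beat_signal(duration = 10, seed = 42)$signal, 20),
               class = "slecg_argument_error")
})

test_that("anchored segmentation starts at the first R peak and drops the remainder", {
  fx <- clean_beat_signal(hr = 70, duration = 35, fs = 100, seed = 43)
  pk <- detectRPeaks(fx$signal)
  first <- peakIndices(pk)[1]
  segs <- segmentSignal(fx$signal, 10, anchor = pk)
  n_expected <- (3500L - first + 1L) %/% 1000L
  expect_length(segments(segs), n_expected)
  expect_equal(startIndices(segs)[1], first)
  expect_equal(diff(startIndices(segs)), rep(1000L, n_expected - 1L))
})

test_that("concatenated segments reproduce the corresponding input slice", {
  fx <- clean_beat_signal(hr = 80, duration = 32, fs = 100, seed = 44)
  pk <- detectRPeaks(fx$signal)
  segs <- segmentSignal(fx$signal, 10, anchor = pk)
  first <- startIndices(segs)[1]
  joined <- unlist(segments(segs))
  expect_identical(joined,
                   samples(fx$signal)[first:(first + length(joined) - 1L)])
  # count identity: floor((len - start + 1) / window)
  expect_length(segments(segs),
                (length(samples(fx$signal)) - first + 1L) %/% 1000L)
})
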