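test_that("Fourier resampling changes length by the rate ratio", {
  set.seed(31)
  s300 <- Signal(rnorm(9000), fs = 300, lead = "SL")
  r <- resampleSignal(s300, 100)
  expect_length(samples(r), 3000L)
  expect_equal(samplingRate(r), 100)
  # identity case
  same <- resampleSignal(s300, 300)
  expect_lt(max(abs(samples(same) - samples(s300))), 1e-9)
  expect_error(resampleSignal(s300, 0), class = "slecg_argument_error")
})

test_that("resampling preserves the location of a spectral peak", {
  t <- (0:8999) / 300
  s <- Signal(sin(2 * pi * 5 * t), fs = 300, lead = "SL")
  r <- resampleSignal(s, 100)
  spec <- Mod(fft(samples(r)))[1:1500]
  # bin k (1-based) holds frequency (k-1) * fs / n = (k-1)/30 Hz
  expect_equal(which.max(spec), 5 * 30 + 1)
})

test_that("amplitude normalization divides by max |x| then clips", {
  s <- Signal(c(0.5, 1.0, -2.0), fs = 100, lead = "SL")
  expect_equal(samples(normalizeAmplitude(s)), c(0.25, 0.5, -1.0))
  # fixed point and degenerate all-zero input
  fp <- Signal(c(-1, 1), fs = 100, lead = "SL")
  expect_equal(samples(normalizeAmplitude(fp)), c(-1, 1))
  z <- Signal(c(0, 0, 0), fs = 100, lead = "SL")
  expect_equal(samples(normalizeAmplitude(z)), c(0, 0, 0))
})

test_that("normalization keeps values in bounds and preserves shape", {
  set.seed(32)
  x <- cumsum(rnorm(500))
  out <- samples(normalizeAmplitude(Signal(x, fs = 100, lead = "SL")))
  expect_true(all(out >= -1 & out <= 1))
  expect_equal(cor(out, x), 1)
})

test_that("polarity detection keys on the sign of the dominant extreme", {
  up <- clean_beat_signal(hr = 60, seed = 33)$signal
  expect_equal(detectDominantPolarity(up), "positive")
  down <- Signal(-samples(up), fs = 100, lead = "SL")
  expect_equal(detectDominantPolarity(down), "negative")
  # biphasic with the larger negative phase
  bi <- synthRecord(synthConfig("norm", duration_s = 10, fs = 100,
                                polarity = "biphasic", seed = 34))
  expect_equal(detectDominantPolarity(signals(bi$record)[[1]]), "negative")
  expect_error(detectDominantPolarity(Signal(1:5, fs = 100)),
               class = "slecg_argument_error")
})

test_that("polarity correction is idempotent and sign-symmetric", {
  up <- clean_beat_signal(hr = 72, seed = 35)$signal
  down <- Signal(-samples(up), fs = 100, lead = "SL")
  c_up <- correctPolarity(up)
  c_down <- correctPolarity(down)
  expect_equal(samples(c_up), samples(up))          # unchanged
  expect_equal(samples(c_down), samples(up))        # negation of input
  expect_equal(samples(correctPolarity(c_down)), samples(c_down))
})

test_that("the full chain maps an inverted smart-device signal to the upright output", {
  base <- synthRecord(synthConfig("norm", duration_s = 30, fs = 300,
                                  heart_rate_bpm = 70, seed = 36))
  sig <- signals(base$record)[[1]]
  inv <- Signal(-samples(sig), fs = 300, lead = "SL")
  h1 <- harmonizeSignal(sig)
  h2 <- harmonizeSignal(inv)
  expect_equal(samplingRate(h1), 100)
  expect_length(samples(h1), 3000L)
  expect_equal(samples(h2), samples(h1), tolerance = 1e-6)
})
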