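## Cross-device harmonization: Fourier resampling to a common rate,
## amplitude normalization into fixed clip bounds, and detection/correction
## of negative lead deflection.  Together these reconcile smart-device
## single-lead recordings (e.g., 30 s @ 300 Hz, arbitrary gain, sometimes
## inverted) with clinical-style training signals (10 s @ 100 Hz).

#' Harmonization configuration
#'
#' @param target_fs common sampling rate the pipeline works at (Hz,
#'   default 100, the clinical training rate).
#' @param clip_bounds two-element numeric `c(x, y)` normalization limits,
#'   default `c(-1, 1)`.
#' @param hp_cutoff high-pass cutoff used before polarity detection (Hz,
#'   default 0.5; removes baseline wander without touching QRS energy).
#' @param hp_order Butterworth filter order (default 4).
#' @return a validated list of class `"harmonize_config"`.
#' @export
harmonizeConfig <- function(target_fs = 100, clip_bounds = c(-1, 1),
                            hp_cutoff = 0.5, hp_order = 4L) {
  if (target_fs <= 0) stop_config("target_fs must be positive")
  if (length(clip_bounds) != 2L || clip_bounds[1] >= clip_bounds[2])
    stop_config("clip_bounds must be c(x, y) with x < y")
  if (hp_cutoff <= 0) stop_config("hp_cutoff must be positive")
  structure(list(target_fs = target_fs, clip_bounds = clip_bounds,
                 hp_cutoff = hp_cutoff, hp_order = as.integer(hp_order)),
            class = "harmonize_config")
}

## FFT-domain resampling of a numeric vector from n to m samples: keep the
## lowest min(n, m) frequency bins, splitting/folding the Nyquist bin so
## that real input yields real output, then scale by m/n.
.fourier_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- fft(x)
  Y <- complex(m)
  N <- min(n, m)
  half <- N %/% 2L
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  if (half >= 1L) {
    neg <- seq_len(half - (1L - N %% 2L))          # negative-frequency bins
    if (length(neg)) Y[m - neg + 1L] <- X[n - neg + 1L]
  }
  if (N %% 2L == 0L) {
    if (m < n) {
      # downsampling: fold the old +/- Nyquist pair into the new Nyquist bin
      Y[half + 1L] <- X[half + 1L] + X[n - half + 1L]
    } else {
      # upsampling: split the old Nyquist bin across the new +/- pair
      Y[half + 1L] <- X[half + 1L] / 2
      Y[m - half + 1L] <- Y[half + 1L]
    }
  }
  # unscaled inverse FFT / m gives ifft; the m/n factor preserves amplitude
  Re(fft(Y, inverse = TRUE)) / n
}

#' Fourier-method resampling
#'
#' Resamples a signal to `target_fs` through the frequency domain (FFT,
#' truncation or zero-padding of the spectrum, inverse FFT), the method the
#' pipeline uses to mitigate sampling-rate differences between devices.
#' The output has `round(length * target_fs / fs)` samples.
#'
#' @param signal a [Signal-class] object.
#' @param target_fs desired sampling rate (Hz, > 0).
#' @return resampled [Signal-class].
#' @examples
#' s <- Signal(sin(2 * pi * 5 * seq(0, 30, length.out = 9001)[-9001]),
#'             fs = 300, lead = "SL")
#' length(samples(resampleSignal(s, 100)))  # 3000
#' @export
resampleSignal <- function(signal, target_fs) {
  if (length(target_fs) != 1L || is.na(target_fs) || target_fs <= 0)
    stop_argument("target_fs must be a single positive number")
  m <- round(length(signal@samples) * target_fs / signal@fs)
  if (m < 1) stop_argument("resampling would leave no samples")
  new("Signal", samples = .fourier_resample(signal@samples, as.integer(m)),
      fs = as.numeric(target_fs), lead = signal@lead, source = signal@source)
}

#' Amplitude normalization
#'
#' Divides the samples by the maximum absolute amplitude (preserving the
#' waveform shape) and clips the result into `bounds`.  An identically
#' zero signal passes through unchanged.
#'
#' @param signal a [Signal-class] object.
#' @param bounds two-element `c(x, y)` clip limits, default `c(-1, 1)`.
#' @return normalized [Signal-class] with all samples in `[x, y]` and
#'   maximum absolute value 1 for nonzero input.
#' @export
normalizeAmplitude <- function(signal, bounds = c(-1, 1)) {
  if (length(bounds) != 2L || bounds[1] >= bounds[2])
    stop_argument("bounds must be c(x, y) with x < y")
  x <- signal@samples
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  x <- pmin(pmax(x, bounds[1]), bounds[2])
  new("Signal", samples = x, fs = signal@fs, lead = signal@lead,
      source = signal@source)
}

## zero-phase Butterworth high-pass used by the polarity detector
.hp_filter <- function(x, fs, cutoff, order) {
  wn <- cutoff / (fs / 2)
  if (wn >= 1) stop_argument("high-pass cutoff must be below Nyquist")
  bt <- signal::butter(order, wn, type = "high")
  as.numeric(signal::filtfilt(bt, x))
}

#' Detect the dominant QRS polarity
#'
#' High-pass filters the signal (zero-phase Butterworth, removing baseline
#' wander) and inspects the sample of maximal absolute amplitude: if its
#' value is negative the dominant deflection is negative.  Ties between
#' equal-magnitude positive and negative extremes count as positive.
#'
#' @param signal a [Signal-class] object.
#' @param config a [harmonizeConfig()] list.
#' @return `"positive"` or `"negative"`.
#' @export
detectDominantPolarity <- function(signal, config = harmonizeConfig()) {
  if (!inherits(config, "harmonize_config"))
    stop_config("config must come from harmonizeConfig()")
  x <- signal@samples
  if (length(x) <= 3L * config$hp_order)
    stop_argument("signal too short for polarity detection (needs > %d samples)",
                  3L * config$hp_order)
  f <- .hp_filter(x, signal@fs, config$hp_cutoff, config$hp_order)
  i_max <- which.max(abs(f))
  if (f[i_max] < 0 && abs(f[i_max]) > max(f)) "negative" else "positive"
}

#' Correct negative lead deflection
#'
#' Negates the signal when [detectDominantPolarity()] reports a negative
#' dominant deflection; otherwise returns it unchanged.  Idempotent.
#'
#' @inheritParams detectDominantPolarity
#' @return polarity-corrected [Signal-class].
#' @export
correctPolarity <- function(signal, config = harmonizeConfig()) {
  if (identical(detectDominantPolarity(signal, config), "negative"))
    new("Signal", samples = -signal@samples, fs = signal@fs,
        lead = signal@lead, source = signal@source)
  else signal
}

#' Full harmonization chain
#'
#' Resample to the target rate, normalize the amplitude into the clip
#' bounds, then detect and correct negative deflection — the first layer
#' of the single-lead prediction pipeline.
#'
#' @inheritParams detectDominantPolarity
#' @return harmonized [Signal-class] at `config$target_fs`.
#' @export
harmonizeSignal <- function(signal, config = harmonizeConfig()) {
  if (!inherits(config, "harmonize_config"))
    stop_config("config must come from harmonizeConfig()")
  s <- resampleSignal(signal, config$target_fs)
  s <- normalizeAmplitude(s, config$clip_bounds)
  correctPolarity(s, config)
}
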