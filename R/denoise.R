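## Wavelet denoising: single- (or multi-) level periodized DWT, robust MAD
## noise estimate from the finest detail band, Donoho-Johnstone universal
## threshold, configurable thresholding rule, reconstruction.

#' Denoising configuration
#'
#' @param wavelet wavelet family (default `"bior3.1"`, a short biorthogonal
#'   spline wavelet that preserves P-wave and QRS morphology well).
#' @param mode boundary-extension mode; only the non-redundant `"periodic"`
#'   (periodization) convention is implemented.
#' @param level decomposition depth (default 1; at 100 Hz this splits the
#'   0-50 Hz band into a 0-25 Hz approximation and a 25-50 Hz detail band).
#' @param threshold_mode one of `"soft"`, `"hard"`, `"garrote"`,
#'   `"greater"`, `"less"` (default `"hard"`, which leaves every retained
#'   coefficient untouched and so avoids smoothing sharp QRS deflections).
#' @return a validated list of class `"denoise_config"`.
#' @examples
#' cfg <- denoiseConfig(threshold_mode = "soft")
#' @export
denoiseConfig <- function(wavelet = "bior3.1", mode = "periodic",
                          level = 1L,
                          threshold_mode = c("hard", "soft", "garrote",
                                             "greater", "less")) {
  threshold_mode <- match.arg(threshold_mode)
  waveletFilters(wavelet)                       # validates the name
  if (!identical(mode, "periodic"))
    stop_config("boundary mode '%s' not supported; use 'periodic'", mode)
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop_config("level must be >= 1")
  structure(list(wavelet = wavelet, mode = mode, level = level,
                 threshold_mode = threshold_mode),
            class = "denoise_config")
}

#' Robust noise-scale estimate from a detail band
#'
#' Estimates the Gaussian noise standard deviation as the median absolute
#' deviation about the median of the band, divided by the Gaussian
#' consistency constant 0.6745.
#'
#' @param detail_band numeric vector of wavelet detail coefficients.
#' @return estimated noise sigma (mV), >= 0.
#' @examples
#' estimateNoiseSigma(c(1, -1, 1, -1))  # 1 / 0.6745
#' @export
estimateNoiseSigma <- function(detail_band) {
  if (length(detail_band) < 1L)
    stop_argument("detail band must contain at least one coefficient")
  if (!all(is.finite(detail_band)))
    stop_argument("detail band contains non-finite values")
  median(abs(detail_band - median(detail_band))) / 0.6745
}

#' Donoho-Johnstone universal threshold
#'
#' @param sigma noise scale (>= 0), typically from [estimateNoiseSigma()].
#' @param n original signal length (>= 1); the threshold is
#'   `sigma * sqrt(2 * log(n))` with the natural logarithm.
#' @return threshold value >= 0.
#' @examples
#' universalThreshold(1.48258, 1000)
#' @export
universalThreshold <- function(sigma, n) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop_argument("signal length n must be >= 1")
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop_argument("sigma must be a single non-negative number")
  sigma * sqrt(2 * log(n))
}

#' Apply a thresholding rule to coefficients
#'
#' The five standard rules: `hard` zeroes coefficients with |c| <= thr and
#' keeps the rest exactly; `soft` additionally shrinks survivors toward
#' zero by thr; `garrote` applies the non-negative garrote shrinkage
#' c - thr^2/c; `greater`/`less` keep only coefficients above/below thr
#' (signed comparison), zeroing the others.
#'
#' @param x numeric coefficient vector.
#' @param thr threshold (>= 0 for soft/hard/garrote).
#' @param mode thresholding rule.
#' @return thresholded vector of the same length.
#' @export
thresholdCoefficients <- function(x, thr,
                                  mode = c("hard", "soft", "garrote",
                                           "greater", "less")) {
  mode <- match.arg(mode)
  switch(mode,
    hard    = ifelse(abs(x) > thr, x, 0),
    soft    = sign(x) * pmax(abs(x) - thr, 0),
    garrote = ifelse(abs(x) > thr, x - thr^2 / x, 0),
    greater = ifelse(x > thr, x, 0),
    less    = ifelse(x < thr, x, 0))
}

#' Wavelet-denoise a signal
#'
#' Decomposes the signal, estimates the noise scale from the finest detail
#' band, computes the universal threshold with `n` equal to the original
#' signal length, applies the configured thresholding rule to every detail
#' band (the approximation band is left untouched), and reconstructs.  The
#' output has the same sampling rate, lead and length as the input.
#'
#' @param signal a [Signal-class] object (or bare numeric vector, in which
#'   case a numeric vector is returned).
#' @param config a [denoiseConfig()] list.
#' @return denoised signal of the same type and length as the input.
#' @examples
#' s <- Signal(sin(2 * pi * 5 * seq(0, 10, by = 0.01)) +
#'             rnorm(1001, sd = 0.3), fs = 100, lead = "I")
#' d <- denoiseSignal(s, denoiseConfig())
#' @export
denoiseSignal <- function(signal, config = denoiseConfig()) {
  if (!inherits(config, "denoise_config"))
    stop_config("config must come from denoiseConfig()")
  is_sig <- is(signal, "Signal")
  x <- if (is_sig) signal@samples else as.numeric(signal)
  if (length(x) < 2^config$level)
    stop_argument("signal of length %d too short for level %d",
                  length(x), config$level)
  dec <- waveletDecompose(x, config$wavelet, config$level)
  finest <- dec$coefficients[[length(dec$coefficients)]]
  sigma <- estimateNoiseSigma(finest)
  thr <- universalThreshold(sigma, length(x))
  for (k in seq_along(dec$coefficients)[-1])   # details only
    dec$coefficients[[k]] <-
      thresholdCoefficients(dec$coefficients[[k]], thr,
                            config$threshold_mode)
  y <- waveletReconstruct(dec)
  y <- y[seq_len(length(x))]                   # guard; lengths match by design
  if (is_sig)
    new("Signal", samples = y, fs = signal@fs, lead = signal@lead,
        source = signal@source)
  else y
}
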