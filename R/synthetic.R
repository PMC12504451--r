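## Synthetic ECG generator.  Beats are sums of Gaussian bumps for the
## P, Q, R, S and T waves placed along a beat train; normal sinus rhythm
## has a regular RR series (small uniform jitter) and a visible P wave,
## while the AFib class has an irregular RR series (coefficient of
## variation >= 0.2), no P wave and a low-amplitude 4-9 Hz fibrillatory
## baseline oscillation.  Device profiles emulate the cross-device
## discrepancies the pipeline must absorb: sampling rate, record length,
## amplitude scale and occasional negative or biphasic lead deflection.

#' Synthetic-record configuration
#'
#' @param rhythm_class `"norm"` or `"afib"`.
#' @param duration_s record length in seconds (default 10).
#' @param fs sampling rate, one of 100, 300, 500 Hz (default 100).
#' @param heart_rate_bpm mean heart rate in \[30, 220\] (default 75).
#' @param amplitude_scale overall gain in mV per unit R amplitude
#'   (default 1).
#' @param polarity `"positive"`, `"negative"` or `"biphasic"` dominant
#'   QRS deflection (default positive).
#' @param noise list of `list(kind=, magnitude=)` entries with kind in
#'   `{"baseline", "powerline", "gaussian"}` and magnitude in mV;
#'   default empty (clean signal).
#' @param seed integer fixing all randomness (default 1).
#' @return a validated list of class `"synth_config"`.
#' @export
synthConfig <- function(rhythm_class = c("norm", "afib"), duration_s = 10,
                        fs = 100, heart_rate_bpm = 75,
                        amplitude_scale = 1,
                        polarity = c("positive", "negative", "biphasic"),
                        noise = list(), seed = 1L) {
  rhythm_class <- match.arg(rhythm_class)
  polarity <- match.arg(polarity)
  if (!fs %in% c(100, 300, 500))
    stop_config("fs must be one of 100, 300, 500 Hz")
  if (duration_s <= 0) stop_config("duration_s must be positive")
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220)
    stop_config("heart_rate_bpm must lie in [30, 220]")
  for (nz in noise) {
    if (!is.list(nz) || !all(c("kind", "magnitude") %in% names(nz)) ||
        !nz$kind %in% c("baseline", "powerline", "gaussian"))
      stop_config("noise entries must be list(kind = 'baseline'|'powerline'|'gaussian', magnitude = mV)")
  }
  structure(list(rhythm_class = rhythm_class, duration_s = duration_s,
                 fs = fs, heart_rate_bpm = heart_rate_bpm,
                 amplitude_scale = amplitude_scale, polarity = polarity,
                 noise = noise, seed = as.integer(seed)),
            class = "synth_config")
}

.gauss_bump <- function(t, center, width, amp) {
  amp * exp(-((t - center)^2) / (2 * width^2))
}

## one P-QRS-T complex centered on the R instant; offsets compress for
## short RR so waves do not collide at high rates
.beat_template <- function(t, r_time, rr, with_p = TRUE) {
  cf <- min(1, rr / 0.6)
  y <- .gauss_bump(t, r_time, 0.012, 1.00) +                 # R
    .gauss_bump(t, r_time - 0.035 * cf, 0.010, -0.10) +      # Q
    .gauss_bump(t, r_time + 0.035 * cf, 0.010, -0.15) +      # S
    .gauss_bump(t, r_time + 0.28 * cf, 0.050 * cf, 0.30)     # T
  if (with_p) y <- y + .gauss_bump(t, r_time - 0.18 * cf, 0.025, 0.15)
  y
}

#' Generate one synthetic ECG record with ground truth
#'
#' @param config a [synthConfig()] list.
#' @return list with `record` (a single-lead [ECGRecord-class], lead
#'   `"SL"`) and `truth` (list of `beat_times` in seconds, `rr_intervals`
#'   and `label`).  Deterministic given `config$seed`.
#' @examples
#' out <- synthRecord(synthConfig("afib", duration_s = 30, fs = 300, seed = 2))
#' out$record
#' @export
synthRecord <- function(config = synthConfig()) {
  if (!inherits(config, "synth_config"))
    stop_config("config must come from synthConfig()")
  set.seed(config$seed)
  fs <- config$fs
  dur <- config$duration_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  mean_rr <- 60 / config$heart_rate_bpm

  # RR series covering the record (start half a beat in)
  beat_times <- numeric()
  rr <- numeric()
  cur <- mean_rr / 2
  while (cur < dur) {
    beat_times <- c(beat_times, cur)
    step <- if (config$rhythm_class == "norm")
      mean_rr * (1 + runif(1, -0.05, 0.05))
    else
      max(0.3, mean_rr * rgamma(1, shape = 16, rate = 16))  # CV = 0.25
    rr <- c(rr, step)
    cur <- cur + step
  }

  x <- numeric(n)
  for (k in seq_along(beat_times))
    x <- x + .beat_template(t, beat_times[k], rr[k],
                            with_p = config$rhythm_class == "norm")

  if (config$rhythm_class == "afib") {
    # fibrillatory baseline: a few random tones in the 4-9 Hz band,
    # below the level-1 wavelet cutoff so denoising keeps the class signal
    for (j in 1:3) {
      fj <- runif(1, 4, 9)
      x <- x + 0.04 * sin(2 * pi * fj * t + runif(1, 0, 2 * pi))
    }
  }

  if (config$polarity == "negative") {
    x <- -x
  } else if (config$polarity == "biphasic") {
    # subtract a delayed, larger negative phase after each R (V1-V3-like)
    for (k in seq_along(beat_times))
      x <- x - .gauss_bump(t, beat_times[k] + 0.02, 0.012, 1.5)
  }

  x <- x * config$amplitude_scale

  sig <- Signal(x, fs = fs, lead = "SL",
                source = sprintf("synthetic seed %d", config$seed))
  for (nz in config$noise)
    sig <- addNoise(sig, nz$kind, nz$magnitude,
                    seed = config$seed + 7919L)

  truth <- list(beat_times = beat_times,
                rr_intervals = if (length(beat_times) > 1) diff(beat_times)
                               else numeric(),
                label = config$rhythm_class)
  rec <- ECGRecord(sig, label = config$rhythm_class,
                   record_id = sprintf("synth_%s_%d", config$rhythm_class,
                                       config$seed))
  list(record = rec, truth = truth)
}

#' Add a noise component to a signal
#'
#' `baseline` is a slow sinusoid (random frequency in 0.2-0.5 Hz),
#' `powerline` a 50 Hz tone, `gaussian` i.i.d. samples; each is added at
#' the stated magnitude in mV (sinusoid amplitude resp. standard
#' deviation).
#'
#' @param signal a [Signal-class].
#' @param kind `"baseline"`, `"powerline"` or `"gaussian"`.
#' @param magnitude noise magnitude in mV (>= 0).
#' @param seed seed for the random components.
#' @return the noisy [Signal-class].
#' @export
addNoise <- function(signal, kind, magnitude, seed = 1L) {
  if (!kind %in% c("baseline", "powerline", "gaussian"))
    stop_config("unknown noise kind '%s'", kind)
  if (magnitude < 0) stop_argument("noise magnitude must be >= 0")
  if (magnitude == 0) return(signal)
  set.seed(seed)
  n <- length(signal@samples)
  t <- (seq_len(n) - 1L) / signal@fs
  add <- switch(kind,
    baseline = magnitude * sin(2 * pi * runif(1, 0.2, 0.5) * t +
                               runif(1, 0, 2 * pi)),
    powerline = magnitude * sin(2 * pi * 50 * t),
    gaussian = rnorm(n, sd = magnitude))
  new("Signal", samples = signal@samples + add, fs = signal@fs,
      lead = signal@lead, source = signal@source)
}

#' Generate a balanced labeled dataset for one device profile
#'
#' Profiles emulate the study's data sources: `clinical_100` (10 s at
#' 100 Hz, unit-scale amplitudes, upright leads), `clinical_500` (10 s at
#' 500 Hz), and `smart_300` (30 s at 300 Hz, roughly doubled amplitude
#' scale and a 20% chance of negative deflection, as smart-device
#' recordings show).  Every record gets mild baseline wander, powerline
#' interference and broadband noise, and its own derived seed.
#'
#' @param n_per_class records per class (>= 1).
#' @param device_profile `"clinical_100"`, `"clinical_500"` or
#'   `"smart_300"`.
#' @param seed master seed; all per-record seeds derive from it.
#' @return list with `records` (list of [synthRecord()] outputs) and
#'   `manifest` (data.frame of id, label, profile, fs, duration, seed).
#' @export
makeDataset <- function(n_per_class, device_profile = c("clinical_100",
                                                        "clinical_500",
                                                        "smart_300"),
                        seed = 1L) {
  device_profile <- match.arg(device_profile)
  if (n_per_class < 1) stop_config("n_per_class must be >= 1")
  prof <- switch(device_profile,
    clinical_100 = list(fs = 100, dur = 10, amp = c(0.8, 1.2), p_neg = 0),
    clinical_500 = list(fs = 500, dur = 10, amp = c(0.8, 1.2), p_neg = 0),
    smart_300    = list(fs = 300, dur = 30, amp = c(1.5, 2.5), p_neg = 0.2))
  set.seed(seed)
  labels <- rep(c("norm", "afib"), each = n_per_class)
  recs <- vector("list", length(labels))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    rseed <- sample.int(2^30, 1L)
    set.seed(rseed)
    hr <- if (labels[i] == "norm") runif(1, 55, 95) else runif(1, 70, 120)
    amp <- runif(1, prof$amp[1], prof$amp[2])
    pol <- if (runif(1) < prof$p_neg) "negative" else "positive"
    cfg <- synthConfig(labels[i], duration_s = prof$dur, fs = prof$fs,
                       heart_rate_bpm = hr, amplitude_scale = amp,
                       polarity = pol,
                       noise = list(
                         list(kind = "baseline", magnitude = 0.05 * amp),
                         list(kind = "powerline", magnitude = 0.02 * amp),
                         list(kind = "gaussian", magnitude = 0.03 * amp)),
                       seed = rseed)
    out <- synthRecord(cfg)
    out$record@record_id <- sprintf("%s_%03d", device_profile, i)
    recs[[i]] <- out
    rows[[i]] <- data.frame(id = out$record@record_id, label = labels[i],
                            profile = device_profile, fs = prof$fs,
                            duration_s = prof$dur, seed = rseed)
  }
  list(records = recs, manifest = do.call(rbind, rows))
}
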