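## Layer 2 of the prediction pipeline: R-peak detection and fixed-length
## segmentation.  Long records (30-60 s) are cut into 10-second windows,
## optionally anchored at the first detected R peak so every window starts
## on a beat.

#' Pan-Tompkins-style R-peak detection
#'
#' Classic QRS detection chain: band-pass 5-15 Hz (zero-phase Butterworth)
#' to isolate QRS energy, differentiate, square, moving-window integrate
#' over 150 ms, then pick peaks of the integrated envelope with an adaptive
#' threshold and a 200 ms refractory period.  Each envelope peak is refined
#' to the largest absolute band-passed deflection within +/-100 ms.
#'
#' @param signal a [Signal-class] object; fs >= 50 Hz, duration >= 2 s.
#' @return an [RPeakList-class] with strictly increasing peak indices.
#' @examples
#' rec <- synthRecord(synthConfig("norm", duration_s = 10, fs = 100, seed = 3))
#' detectRPeaks(signals(rec$record)[[1]])
#' @export
detectRPeaks <- function(signal) {
  fs <- signal@fs
  x <- signal@samples
  if (fs < 50) stop_argument("R-peak detection needs fs >= 50 Hz (got %g)", fs)
  if (length(x) / fs < 2) stop_argument("R-peak detection needs >= 2 s of signal")

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  f <- as.numeric(signal::filtfilt(bp, x))
  d <- c(0, diff(f))
  sq <- d^2
  w <- max(1L, round(0.150 * fs))
  env <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0

  if (max(env) <= 0) return(new("RPeakList", indices = integer(), fs = fs))

  # adaptive threshold: fraction of a high quantile of the envelope,
  # floored well above numerical noise for flat inputs
  thr <- 0.25 * quantile(env, 0.99, names = FALSE)
  refractory <- round(0.200 * fs)
  half_win <- round(0.100 * fs)

  above <- env > thr
  peaks <- integer()
  i <- 1L
  n <- length(env)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      seg <- i:j
      p <- seg[which.max(env[seg])]
      lo <- max(1L, p - half_win)
      hi <- min(n, p + half_win)
      r <- (lo:hi)[which.max(abs(f[lo:hi]))]
      if (!length(peaks) || r - peaks[length(peaks)] > refractory)
        peaks <- c(peaks, r)
      else if (abs(f[r]) > abs(f[peaks[length(peaks)]]))
        peaks[length(peaks)] <- r
      i <- j + refractory
    }
    i <- i + 1L
  }
  new("RPeakList", indices = as.integer(sort(unique(peaks))), fs = fs)
}

#' Cut a signal into fixed-duration segments
#'
#' Produces contiguous, non-overlapping windows of
#' `round(seg_seconds * fs)` samples.  If `anchor` holds at least one R
#' peak, the first window starts at that peak, so that a 30-60 s record
#' yields three or more beat-aligned 10-second fragments; otherwise
#' windowing starts at the first sample.  A trailing partial window is
#' dropped (every rendered image must represent a full window).
#'
#' @param signal a [Signal-class] object.
#' @param seg_seconds window duration in seconds (default 10).
#' @param anchor optional [RPeakList-class] for beat alignment.
#' @return a [SegmentSet-class].
#' @examples
#' rec <- synthRecord(synthConfig("norm", duration_s = 30, fs = 100, seed = 3))
#' segmentSignal(signals(rec$record)[[1]], 10)
#' @export
segmentSignal <- function(signal, seg_seconds = 10, anchor = NULL) {
  fs <- signal@fs
  x <- signal@samples
  win <- round(seg_seconds * fs)
  if (win < 1) stop_argument("segment duration too short at fs %g", fs)
  if (length(x) < win)
    stop_argument(
      "signal duration %.2f s shorter than one %.2f s segment (needs >= %d samples)",
      length(x) / fs, seg_seconds, win)
  start <- 1L
  if (!is.null(anchor)) {
    if (!is(anchor, "RPeakList"))
      stop_argument("anchor must be an RPeakList")
    if (length(anchor@indices) > 0L) start <- anchor@indices[1L]
  }
  n_seg <- (length(x) - start + 1L) %/% win
  if (n_seg < 1L)
    stop_argument("no full %.2f s segment fits after anchor offset %d",
                  seg_seconds, start)
  offs <- start + (seq_len(n_seg) - 1L) * win
  segs <- lapply(offs, function(o) x[o:(o + win - 1L)])
  new("SegmentSet", segments = segs, seg_seconds = as.numeric(seg_seconds),
      fs = fs, start_indices = as.integer(offs),
      source_id = if (nzchar(signal@source)) signal@source else signal@lead)
}
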