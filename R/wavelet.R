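## Periodized discrete wavelet transform.
##
## A self-contained two-channel filter-bank DWT with circular (periodized)
## boundary handling: decimated analysis by circular convolution with the
## decomposition pair, synthesis by upsampling + circular convolution with
## the reconstruction pair.  With the biorthogonal filter banks shipped
## below the analysis/synthesis chain is a pure circular delay, which is
## undone explicitly, giving exact perfect reconstruction on any length.

## Filter banks (dec_lo, dec_hi, rec_lo, rec_hi), standard published
## coefficients.  All four filters of a family share one length.
.wavelet_bank <- local({
  s2 <- sqrt(2)
  list(
    haar = list(
      dec_lo = c(1, 1) / s2,
      dec_hi = c(-1, 1) / s2,
      rec_lo = c(1, 1) / s2,
      rec_hi = c(1, -1) / s2),
    db2 = list(
      dec_lo = c(-0.12940952255126037, 0.22414386804201339,
                 0.83651630373780794, 0.48296291314453416),
      dec_hi = c(-0.48296291314453416, 0.83651630373780794,
                 -0.22414386804201339, -0.12940952255126037),
      rec_lo = c(0.48296291314453416, 0.83651630373780794,
                 0.22414386804201339, -0.12940952255126037),
      rec_hi = c(-0.12940952255126037, -0.22414386804201339,
                 0.83651630373780794, -0.48296291314453416)),
    db4 = list(
      dec_lo = c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854, 0.63088076792985890,
                 0.71484657055291565, 0.23037781330889650),
      dec_hi = c(-0.23037781330889650, 0.71484657055291565,
                 -0.63088076792985890, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                 -0.0328830116668852, -0.010597401785069032),
      rec_lo = c(0.23037781330889650, 0.71484657055291565,
                 0.63088076792985890, -0.027983769416859854,
                 -0.18703481171909309, 0.030841381835560764,
                 0.0328830116668852, -0.010597401785069032),
      rec_hi = c(-0.010597401785069032, -0.0328830116668852,
                 0.030841381835560764, 0.18703481171909309,
                 -0.027983769416859854, -0.63088076792985890,
                 0.71484657055291565, -0.23037781330889650)),
    sym4 = list(
      dec_lo = c(-0.075765714789273330, -0.029635527645998510,
                 0.497618667632015450, 0.803738751805916100,
                 0.297857795605277360, -0.099219543576847220,
                 -0.012603967262037833, 0.032223100604042700),
      dec_hi = c(-0.032223100604042700, -0.012603967262037833,
                 0.099219543576847220, 0.297857795605277360,
                 -0.803738751805916100, 0.497618667632015450,
                 0.029635527645998510, -0.075765714789273330),
      rec_lo = c(0.032223100604042700, -0.012603967262037833,
                 -0.099219543576847220, 0.297857795605277360,
                 0.803738751805916100, 0.497618667632015450,
                 -0.029635527645998510, -0.075765714789273330),
      rec_hi = c(-0.075765714789273330, 0.029635527645998510,
                 0.497618667632015450, -0.803738751805916100,
                 0.297857795605277360, 0.099219543576847220,
                 -0.012603967262037833, -0.032223100604042700)),
    sym6 = list(
      dec_lo = c(0.015404109327027373, 0.0034907120842174702,
                 -0.11799011114819057, -0.048311742585633,
                 0.4910559419267466, 0.787641141030194,
                 0.3379294217276218, -0.07263752278646252,
                 -0.021060292512300564, 0.04472490177066578,
                 0.0017677118642428036, -0.007800708325034148),
      dec_hi = c(0.007800708325034148, 0.0017677118642428036,
                 -0.04472490177066578, -0.021060292512300564,
                 0.07263752278646252, 0.3379294217276218,
                 -0.787641141030194, 0.4910559419267466,
                 0.048311742585633, -0.11799011114819057,
                 -0.0034907120842174702, 0.015404109327027373),
      rec_lo = c(-0.007800708325034148, 0.0017677118642428036,
                 0.04472490177066578, -0.021060292512300564,
                 -0.07263752278646252, 0.3379294217276218,
                 0.787641141030194, 0.4910559419267466,
                 -0.048311742585633, -0.11799011114819057,
                 0.0034907120842174702, 0.015404109327027373),
      rec_hi = c(0.015404109327027373, -0.0034907120842174702,
                 -0.11799011114819057, 0.048311742585633,
                 0.4910559419267466, -0.787641141030194,
                 0.3379294217276218, 0.07263752278646252,
                 -0.021060292512300564, -0.04472490177066578,
                 0.0017677118642428036, 0.007800708325034148)),
    coif1 = list(
      dec_lo = c(-0.015655728135791993, -0.07273261951252645,
                 0.3848648468648578, 0.8525720202116004,
                 0.3378976624574818, -0.07273261951252645),
      dec_hi = c(0.07273261951252645, 0.3378976624574818,
                 -0.8525720202116004, 0.3848648468648578,
                 0.07273261951252645, -0.015655728135791993),
      rec_lo = c(-0.07273261951252645, 0.3378976624574818,
                 0.8525720202116004, 0.3848648468648578,
                 -0.07273261951252645, -0.015655728135791993),
      rec_hi = c(-0.015655728135791993, 0.07273261951252645,
                 0.3848648468648578, -0.8525720202116004,
                 0.3378976624574818, 0.07273261951252645)),
    bior3.1 = list(
      dec_lo = c(-0.3535533905932738, 1.0606601717798212,
                 1.0606601717798212, -0.3535533905932738),
      dec_hi = c(-0.1767766952966369, 0.5303300858899106,
                 -0.5303300858899106, 0.1767766952966369),
      rec_lo = c(0.1767766952966369, 0.5303300858899106,
                 0.5303300858899106, 0.1767766952966369),
      rec_hi = c(-0.3535533905932738, -1.0606601717798212,
                 1.0606601717798212, 0.3535533905932738)),
    bior3.3 = list(
      dec_lo = c(0.06629126073623882, -0.19887378220871650,
                 -0.15467960838455727, 0.99436891104358250,
                 0.99436891104358250, -0.15467960838455727,
                 -0.19887378220871650, 0.06629126073623882),
      dec_hi = c(0, 0, -0.1767766952966369, 0.5303300858899106,
                 -0.5303300858899106, 0.1767766952966369, 0, 0),
      rec_lo = c(0, 0, 0.1767766952966369, 0.5303300858899106,
                 0.5303300858899106, 0.1767766952966369, 0, 0),
      rec_hi = c(0.06629126073623882, 0.19887378220871650,
                 -0.15467960838455727, -0.99436891104358250,
                 0.99436891104358250, 0.15467960838455727,
                 -0.19887378220871650, -0.06629126073623882)),
    bior2.8 = list(
      dec_lo = c(0, 0.0015105430506304422, -0.0030210861012608843,
                 -0.012947511862546647, 0.028916109826354180,
                 0.052998481890690940, -0.134913073607736050,
                 -0.163829183434090230, 0.462571440475916530,
                 0.951642121897178600, 0.462571440475916530,
                 -0.163829183434090230, -0.134913073607736050,
                 0.052998481890690940, 0.028916109826354180,
                 -0.012947511862546647, -0.0030210861012608843,
                 0.0015105430506304422),
      dec_hi = c(0, 0, 0, 0, 0, 0, 0, 0.3535533905932738,
                 -0.7071067811865476, 0.3535533905932738,
                 0, 0, 0, 0, 0, 0, 0, 0),
      rec_lo = c(0, 0, 0, 0, 0, 0, 0, 0.3535533905932738,
                 0.7071067811865476, 0.3535533905932738,
                 0, 0, 0, 0, 0, 0, 0, 0),
      rec_hi = c(0, -0.0015105430506304422, -0.0030210861012608843,
                 0.012947511862546647, 0.028916109826354180,
                 -0.052998481890690940, -0.134913073607736050,
                 0.163829183434090230, 0.462571440475916530,
                 -0.951642121897178600, 0.462571440475916530,
                 0.163829183434090230, -0.134913073607736050,
                 -0.052998481890690940, 0.028916109826354180,
                 0.012947511862546647, -0.0030210861012608843,
                 -0.0015105430506304422)),
    rbio1.5 = list(
      dec_lo = c(0, 0, 0, 0, 0.7071067811865476, 0.7071067811865476,
                 0, 0, 0, 0),
      dec_hi = c(-0.016572815184059706, -0.016572815184059706,
                 0.121533978016437850, 0.121533978016437850,
                 -0.707106781186547600, 0.707106781186547600,
                 -0.121533978016437850, -0.121533978016437850,
                 0.016572815184059706, 0.016572815184059706),
      rec_lo = c(0.016572815184059706, -0.016572815184059706,
                 -0.121533978016437850, 0.121533978016437850,
                 0.707106781186547600, 0.707106781186547600,
                 0.121533978016437850, -0.121533978016437850,
                 -0.016572815184059706, 0.016572815184059706),
      rec_hi = c(0, 0, 0, 0, 0.7071067811865476, -0.7071067811865476,
                 0, 0, 0, 0))
  )
})

#' Names of the wavelet families shipped with the package
#' @return character vector of wavelet names accepted by [denoiseConfig()].
#' @export
availableWavelets <- function() names(.wavelet_bank)

waveletFilters <- function(wavelet) {
  if (!wavelet %in% names(.wavelet_bank))
    stop_config("unknown wavelet '%s'; available: %s", wavelet,
                paste(availableWavelets(), collapse = ", "))
  .wavelet_bank[[wavelet]]
}

## circular convolution y[i] = sum_j f[j] x[(i - j) mod n]
.circconv <- function(x, f) {
  n <- length(x)
  idx <- seq_len(n) - 1L
  y <- numeric(n)
  for (j in seq_along(f)) {
    if (f[j] != 0) y <- y + f[j] * x[((idx - (j - 1L)) %% n) + 1L]
  }
  y
}

## One analysis step on an even-length vector.
.dwt_step <- function(x, flt) {
  n <- length(x)
  keep <- seq(2L, n, by = 2L)
  list(a = .circconv(x, flt$dec_lo)[keep],
       d = .circconv(x, flt$dec_hi)[keep])
}

## One synthesis step; `delay` undoes the circular delay of the chain
## (filter length - 1 for the equal-length banks above; verified by the
## perfect-reconstruction tests for every shipped family).
.idwt_step <- function(a, d, flt) {
  n <- 2L * length(a)
  u <- v <- numeric(n)
  slots <- seq(2L, n, by = 2L)
  u[slots] <- a
  v[slots] <- d
  r <- .circconv(u, flt$rec_lo) + .circconv(v, flt$rec_hi)
  delay <- length(flt$rec_lo) - 1L
  if (delay > 0L) r[(((seq_len(n) - 1L) + delay) %% n) + 1L] else r
}

#' Multi-level periodized wavelet decomposition
#'
#' Decomposes a numeric vector into an approximation band and `level`
#' detail bands with circular boundary handling.  Odd-length bands are
#' extended by repeating their final sample before each split; the original
#' band lengths are recorded so that [waveletReconstruct()] restores the
#' exact input length.
#'
#' @param x numeric vector, length >= 2^level.
#' @param wavelet wavelet family name (see [availableWavelets()]).
#' @param level decomposition depth (>= 1).
#' @return A list of class `"wavelet_decomposition"` with elements
#'   `coefficients` (approximation first, then details coarsest to finest),
#'   `lengths` (pre-split band lengths per level), `wavelet`, `level`, `n`.
#' @examples
#' dec <- waveletDecompose(sin(seq(0, 10, length.out = 256)), "bior3.1", 1)
#' lengths(dec$coefficients)
#' @export
waveletDecompose <- function(x, wavelet = "bior3.1", level = 1L) {
  flt <- waveletFilters(wavelet)
  level <- as.integer(level)
  if (level < 1L) stop_argument("decomposition level must be >= 1")
  if (length(x) < 2^level)
    stop_argument("signal of length %d too short for level %d (needs >= %d samples)",
                  length(x), level, 2^level)
  details <- vector("list", level)
  lens <- integer(level)
  a <- as.numeric(x)
  for (l in seq_len(level)) {
    lens[l] <- length(a)
    if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
    st <- .dwt_step(a, flt)
    a <- st$a
    details[[l]] <- st$d
  }
  structure(list(
    coefficients = c(list(a), rev(details)),
    lengths = lens, wavelet = wavelet, level = level, n = length(x)
  ), class = "wavelet_decomposition")
}

#' Reconstruct a signal from a wavelet decomposition
#'
#' Inverse of [waveletDecompose()]; with unmodified coefficient bands the
#' input is reproduced exactly (periodized perfect reconstruction).
#'
#' @param dec a `"wavelet_decomposition"` as returned by
#'   [waveletDecompose()], possibly with thresholded detail bands.
#' @return numeric vector of length `dec$n`.
#' @export
waveletReconstruct <- function(dec) {
  if (!inherits(dec, "wavelet_decomposition"))
    stop_argument("expected a wavelet_decomposition object")
  flt <- waveletFilters(dec$wavelet)
  a <- dec$coefficients[[1]]
  details <- rev(dec$coefficients[-1])   # back to finest-last order
  for (l in rev(seq_len(dec$level))) {
    a <- .idwt_step(a, details[[l]], flt)
    a <- a[seq_len(dec$lengths[l])]      # drop odd-length padding
  }
  a
}
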