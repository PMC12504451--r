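---
title: "Methods: single-lead ECG atrial-fibrillation screening with slecg"
author: "slecg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-lead ECG atrial-fibrillation screening with slecg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wearable and handheld ECG devices record a single lead — typically 30 s at
300 Hz with lead-I-like morphology — while the labeled data that deep
models are trained on comes from clinical 12-lead machines (10 s records
at 100 or 500 Hz). A classifier trained on clinical signals and deployed
on smart-device signals therefore faces three systematic mismatches:
sampling rate, amplitude scale, and occasional inverted (negative or
biphasic) lead deflection from electrode placement. **slecg** implements a
complete pipeline that absorbs these mismatches and classifies atrial
fibrillation (AFib) versus normal sinus rhythm from one lead:

1. **Denoise** — periodized discrete wavelet transform, robust noise
   estimate, universal threshold.
2. **Harmonize** — Fourier resampling to a common rate, amplitude
   normalization into $[-1, 1]$, polarity detection and correction.
3. **Segment** — fixed 10-second windows, anchored at the first detected
   R peak for long records.
4. **Render** — each window becomes a deterministic 96×96 grayscale
   image.
5. **Classify** — a compact four-block 2-D CNN scores each image with a
   sigmoid output (≈1 normal, ≈0 disease).
6. **Vote** — per-segment confidences are summed per class and the larger
   sum wins, so one confident AFib segment can overrule two uncertain
   normal ones.

A synthetic ECG generator reproduces the class structure and the
cross-device discrepancies, so every stage is testable without clinical
data.

## Wavelet denoising

A signal $x$ of length $n$ is decomposed with a two-channel filter bank
(default `bior3.1`, level 1) under circular ("periodized") boundary
handling. The noise scale is estimated from the finest detail band $d$ as

$$\hat\sigma = \frac{\mathrm{median}\,|d - \mathrm{median}(d)|}{0.6745},$$

the Donoho–Johnstone universal threshold is
$T = \hat\sigma\sqrt{2\ln n}$, and the configured rule (default `hard`)
is applied to every detail band; the approximation band is untouched.
Reconstruction truncates to the original length, so odd-length inputs are
handled exactly.

Choices worth noting:

* The robust scale estimator is the **median** absolute deviation. The
  constant 0.6745 is the Gaussian consistency constant for the median
  (it is *not* consistent for the mean absolute deviation), so the
  estimator and constant are kept internally consistent.
* $n$ in the threshold is the **original signal length**, and
  $\hat\sigma$ comes from the finest detail band only — the standard
  wavelet-shrinkage convention.
* Only the non-redundant periodization convention is implemented for the
  boundary mode; it gives exact perfect reconstruction at every length,
  which the test suite asserts to $10^{-8}$ relative error for every
  shipped filter bank (haar, db2, db4, sym4, sym6, coif1, bior3.1,
  bior3.3, bior2.8, rbio1.5).
* Detail-only thresholding was chosen over thresholding all bands:
  shrinking the approximation band would attenuate the ECG itself rather
  than noise.
* `hard` is the default rule because it leaves every retained coefficient
  exactly as observed, avoiding the QRS smoothing that `soft` shrinkage
  introduces. `garrote`, `greater` and `less` follow their standard
  definitions.

At 100 Hz and level 1 the approximation band covers 0–25 Hz and the
detail band 25–50 Hz; the suite verifies this by reconstructing pure
tones with zeroed details (a 10 Hz tone survives, a 40 Hz tone is
strongly attenuated).

## Harmonization

* **Resampling** is done in the frequency domain: FFT, truncation or
  zero-padding of the spectrum with Nyquist-bin folding/splitting,
  inverse FFT, scaling by $m/n$. This is the classical Fourier method;
  it preserves spectral peak locations exactly for band-limited content.
* **Normalization** divides by $\max|x|$ and clips into the configured
  bounds (default $[-1,1]$). Dividing by the signed maximum — the naive
  reading of "divide by max" — would invert all-negative signals and is
  ill-defined near zero; $\max|x|$ preserves the waveform shape for any
  deflection, and an identically zero signal passes through unchanged.
* **Polarity** is detected on a zero-phase Butterworth high-passed copy
  (default 0.5 Hz, order 4 — removes baseline wander, leaves QRS energy).
  The sample of maximal absolute amplitude decides: if its value is
  negative, the dominant deflection is negative and the signal is
  negated. A tie between equal positive and negative extremes counts as
  positive — the signal is only flipped on clear evidence. The operation
  is idempotent and maps a signal and its negation to the same output.

The pipeline order is denoise → harmonize. Denoising first means the
polarity decision and the normalization peak are not driven by noise
spikes; the order is configurable through `pipelineConfig()`.

## Segmentation and rendering

Windows hold exactly `round(seg_seconds * fs)` samples (default 10 s)
and trailing partial windows are dropped, because every image fed to the
CNN must represent a full 10 s. Two windowing modes exist. The
*prediction* path cuts successive windows from the start of the record,
so a 30 s device recording yields exactly three fragments — windows
anchored at the first R peak (typically ~0.5 s in) would sacrifice the
trailing window and leave only two. *Beat-aligned anchoring*
(`anchor_rpeaks = TRUE`, or an explicit `RPeakList` passed to
`segmentSignal()`) starts the first window at the first detected R peak
and is intended for preparing training images from long clinical
records, where aligning windows to beats is worth a dropped tail. The
R-peak detector is a
Pan–Tompkins-style chain (band-pass 5–15 Hz, differentiate, square,
150 ms moving integration, adaptive threshold, 200 ms refractory period)
implemented in the package so the stage is a tested, self-contained
computation; its sensitivity and positive predictive value exceed 95% on
noiseless synthetic trains from 50 to 150 bpm.

Rendering maps time to columns and amplitude to rows (+1 at the top). For
each of the 96 columns the min–max envelope of its samples is drawn as a
filled vertical run of 1-valued pixels on a 0 background — no axes,
margins, or anti-aliasing, and no plotting backend, so images are
byte-for-byte deterministic. Pixel rows are treated as closed amplitude
intervals, which makes amplitude negation an *exact* vertical mirror of
the image (a property the tests assert pixelwise). PNG export inverts
intensities (trace black on white) for human viewing.

## The CNN

Architecture (input 96×96×1):

| block | layer | output | trainable parameters |
|---|---|---|---|
| 1 | conv 3×3, 32 filters, same, ReLU; max-pool 2×2; dropout 0.25 | 48×48×32 | 320 |
| 2 | conv 3×1, 64 filters, same, ReLU; max-pool 2×2; dropout 0.25 | 24×24×64 | 6 208 |
| 3 | conv 3×1, 128 filters, same, ReLU; max-pool 2×2; dropout 0.40 | 12×12×128 | 24 704 |
| 4 | conv 3×1, 128 filters, same, ReLU; max-pool 3×2; dropout 0.50 | 4×6×128 | 49 280 |
| | flatten (3072); dropout 0.50; dense 96, ReLU | 96 | 295 008 |
| | dense 1, sigmoid | 1 | 97 |

The five named components sum to 375 520 trainable parameters (375 617
including the output layer). The kernel and pooling schedule is pinned
down by these counts: 320 parameters in a 32-filter first layer force a
3×3 single-channel kernel; 6 208 in the second force 3×1 kernels from 32
channels; and a dense fan-in of 3072 ($295\,008 = 96 \times 3073$)
requires the pool schedule (2,2), (2,2), (2,2), (3,2) on a 96×96 input.
`countParameters()` verifies the closed-form identities against the
dimensions of the actual weight arrays on every call.

Pooling uses floor division, so non-default input sizes (e.g. 95×95)
build cleanly with a smaller flatten; the documented shapes are part of
the contract and tested.

The network is trained with binary cross-entropy and Adam. The loss is
binary (one sigmoid unit) rather than a multi-class softmax with a norm
penalty: the binary output layer fixes the loss family, and dropout
provides the regularization. Training details, all overridable:

* learning rate $10^{-3}$, batch 32, Glorot-uniform initialization;
* stratified 20% validation split, early stopping on validation loss
  (patience 8) with best-weights restoration;
* default epoch budget 40. On the package's reference synthetic task
  (400 images, separable by construction) optimization shows a plateau
  near chance for roughly ten epochs before the loss drops and
  validation accuracy reaches 1.0 around epoch 30; 40 epochs with
  patience 8 gives the run room to pass the plateau while early stopping
  trims it once converged.
* every random choice (initialization, shuffling, dropout masks,
  validation split) derives from one seed, so histories are exactly
  reproducible; dropout is disabled at inference, so repeated prediction
  is bit-identical.

The engine itself (im2col + BLAS GEMM forward, mirrored backward,
max-pool argmax bookkeeping fused with the ReLU derivative) is compiled
code in `src/`; its gradients are verified against central differences in
development and its training behavior is exercised end to end in the
tests.

## Decision layer

Per segment, the sigmoid score $s$ is thresholded (norm iff
$s \ge t$, default $t = 0.5$) and mapped to a confidence: $s$ for a
norm label, $1 - s$ for an afib label — this puts both classes'
confidences on the same $[0,1]$ scale so their sums are comparable. The
vote compares $S_{\text{norm}}$ and $S_{\text{afib}}$ and applies to any
segment count; an exact tie returns afib, favoring sensitivity in a
screening context. `sweepThreshold()` scans a grid for the most accurate
boundary, breaking ties toward 0.5 (extreme cutoffs generalize poorly)
and then toward the smaller value. For record-level ROC analysis the
per-record score is the mean sigmoid score across segments.

## Metrics

With afib as the positive class: sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$ (a zero denominator yields a flagged `NA`, never 0), and
AUROC by the trapezoidal rule over all distinct score thresholds,

$$\mathrm{AUC} \approx \sum_i \tfrac12 (TPR_i + TPR_{i+1})(FPR_{i+1} - FPR_i),$$

which equals the Mann–Whitney pairwise probability with half credit for
ties; the suite checks this identity against a brute-force pairwise
oracle to $10^{-12}$ and cross-checks an established ROC implementation.

## The synthetic generator

Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) with fixed
relative timings that compress for short RR intervals. The classes differ
in exactly the three canonical surface features of AFib:

* **rhythm** — normal RR jitter is uniform ±5% (CV ≈ 0.03); AFib RR
  multipliers are Gamma(16,16) (CV 0.25, floored at 0.3 s);
* **P wave** — present in normal, absent in AFib;
* **fibrillatory baseline** — AFib adds three random tones in 4–9 Hz at
  0.04 mV each, deliberately below the 25 Hz level-1 wavelet boundary so
  denoising cannot erase the class signal.

Device profiles fix the study conditions: `clinical_100` (10 s, 100 Hz,
amplitude scale 0.8–1.2, upright), `clinical_500` (500 Hz), `smart_300`
(30 s, 300 Hz, amplitude scale 1.5–2.5, 20% negative deflection). All
profiles add mild baseline wander (0.05×scale mV), 50 Hz interference
(0.02×scale) and broadband noise (0.03×scale). Heart rates are drawn
per record (normal 55–95 bpm, AFib 70–120 bpm). Everything derives from
one master seed.

What the generator does *not* emulate: real P/QRS/T morphology variation
across subjects, ectopy, motion artifacts, muscle noise bursts, or
12-lead vector projections. Passing the synthetic cross-device experiment
therefore shows that the pipeline's stages compose correctly and that the
harmonization absorbs rate/amplitude/polarity mismatch — it does not
certify clinical performance, which requires the real datasets the
pipeline's readers can obtain themselves.

## Reference experiment and problem sizes

The package's reference experiment trains on 400 synthetic clinical
records (200 per class, 10 s at 100 Hz — one image each) and tests on 100
synthetic smart-device records (50 per class, 30 s at 300 Hz — three
voted segments each) through the full chain. At the default seeds the
trained model reaches validation accuracy 1.0 and record-level test
accuracy 1.0; the acceptance test requires ≥ 0.90. These sizes keep the
whole suite desk-scale (minutes on one CPU) while leaving the class
separation non-trivial (single-image accuracy mid-training is far from
perfect; voting adds the final margin).

## Known limitations

* Only the periodization boundary mode is implemented; redundant
  (stationary) wavelet variants are out of scope.
* The MAT reader handles the single-matrix uncompressed v5 layout used
  by the public ECG challenge datasets, not general MAT files; the WFDB
  reader handles format 16.
* The CNN engine is single-threaded per GEMM call and sized for this
  architecture class, not a general deep-learning framework.
* Per-lead polarity priors (e.g. never flipping aVR) are deliberately not
  applied; harmonization treats the test-side single lead uniformly.
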