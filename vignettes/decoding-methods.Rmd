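---
title: "Decoding reach kinematics from ECoG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding reach kinematics from ECoG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decoding problem

Subdural electrocorticography (ECoG) records cortical field potentials whose
spectral power co-modulates with movement: high-gamma power (>70 Hz)
increases with local cortical activation, while the low-frequency
sensorimotor rhythms (mu, beta, and often delta/theta) desynchronize — their
power drops — during movement. The heavily smoothed time-domain amplitude
(the local motor potential, LMP) carries additional movement information
with no consistent sign.

`ecogreach` decodes a low-dimensional representation of unconstrained 3-D
reaching from these signals. Because naturalistic reaches to scattered
targets do not probe the Cartesian axes independently, the kinematic
dimensions are correlated; the package therefore decorrelates them by
principal component analysis and treats the first PC — the dominant movement
axis — as the primary decoding target.

## The analysis chain

1. **Common average reference.** Each channel minus the instantaneous
   cross-channel mean, removing reference-placement bias. At least two
   channels are required.
2. **Filter bank.** Seven zero-phase band-pass filters: delta (0–4 Hz,
   realized as a low-pass since a 0 Hz edge is not realizable as band-pass),
   theta (4–8), mu (7–13), beta (14–30), low gamma (30–50), high gamma 1
   (70–110), high gamma 2 (130–200). Each is a 401-tap (order-400)
   Hamming-window FIR filter applied forward and backward, so passband
   signals incur no delay; band edges avoid 60 Hz line noise and its
   harmonics. "Order 400" is interpreted as 400 delay elements, i.e. 401
   taps, the common DSP convention.
3. **Band power.** Filtered signals are downsampled to the 100 Hz kinematic
   rate (every 10th sample; the band filter is the only anti-alias
   filtering, so the two high-gamma carriers alias — their variance, and
   hence the smoothed power envelope, is preserved), squared, smoothed with
   a 1 s moving average applied forward and backward (a triangular kernel,
   zero net phase), and log-transformed with a guard,
   `log(p + 1e-12)`, so silent channels stay finite. An `envelope_first`
   option squares and smooths at 1 kHz before downsampling for users who
   prefer an anti-aliased envelope; the default order is the canonical one.
4. **LMP.** A 2 s forward-backward moving average of the CAR'd signal at
   1 kHz, then decimated to 100 Hz; units remain microvolts. Smoothing
   before decimation avoids aliasing the residual fast structure.
5. **Trimming.** Filter and smoother transients at the block edges are
   removed by trimming 2 s (the largest smoothing window) from both ends of
   the features and the kinematics jointly.
6. **Per-fold transforms.** Within each cross-validation fold, the
   kinematics are z-scored and a 3x3 PCA is fitted *on the training block
   only*; test data are transformed with the training statistics. PCA signs
   are arbitrary, so each component is flipped to make its largest-magnitude
   loading positive, keeping loadings comparable across folds.
7. **Feature selection.** Every (channel, feature type) candidate is scored
   by its Pearson correlation with the target over lags of ±1 s in 50 ms
   steps (negative lag = neural change precedes kinematics), computed over
   the overlapping samples only. Each candidate enters at most once, at its
   best lag; candidates are ranked by |r|, since informative low-frequency
   features correlate *negatively*. Ties break deterministically (channel
   index, feature order, smaller |lag|, earlier lag).
8. **Decoder.** Ordinary least squares: the target is a linear combination
   of the selected, z-scored, lag-aligned features plus an intercept and
   Gaussian noise. Default model size is 9 inputs.
9. **Evaluation.** Fivefold cross-validation with *contiguous* test blocks:
   the 1–2 s smoothing induces strong autocorrelation that random-sample
   folds would leak across the train/test boundary. Accuracy is Pearson's r
   between held-out predictions and observations, optionally mapped to
   Fisher z = atanh(r)·sqrt(n−3) with n the evaluated test samples. Samples
   whose lag sources fall outside their own block (train or test) are
   dropped, so no statistic ever mixes the two.

All feature extraction is explicitly non-causal (forward-backward filters,
centered smoothing, two-sided lags); a causal mode with its group delay is
out of scope.

## Chance calibration and the statistical analyses

Decoding accuracy on smoothed, autocorrelated signals can look impressive by
accident. Chance level is therefore measured by decoupling features from
kinematics and rerunning the *entire* pipeline — selection included — on
each surrogate:

- `circular_shift` (default): each feature's time axis is rotated by an
  independent uniform shift in [5 s, T−5 s]. This preserves each feature's
  autocorrelation, giving a realistic null.
- `permute`: independent sample-wise permutation per feature. This destroys
  autocorrelation and yields a more permissive null; it is provided for
  users who want the literal shuffling reading.

The null records, per surrogate, both the median-over-folds accuracy (used
for the chance band and the null maximum) and the per-fold accuracies. The
Wilcoxon rank-sum comparison of actual versus chance uses the *fold-level*
surrogate accuracies as its reference sample: fold accuracies and
medians-of-folds have different dispersion under the null, and comparing
across those two statistics inflates the one-sided rejection rate well above
its nominal level.

Supporting analyses follow standard forms: Bonferroni correction over
simultaneous target comparisons; a fixed-effects two-way ANOVA of Fisher-z
accuracies with model size and feature type as factors, with Dunn-Šidák
corrected pairwise post-hoc t comparisons (per-test level
`1-(1-alpha)^(1/m)`); and a Kruskal–Wallis test across model sizes followed
by an LSD-style Conover rank post-hoc that reports the smallest model size
beyond which no larger model is significantly better.

## The synthetic session generator

No patient recordings accompany this package, so every stage is validated on
synthetic sessions whose ground truth is known and stored alongside the
data.

**Kinematics.** Rests at a home position (bottom-front-center of the
workspace box) alternate with reach epochs to targets drawn uniformly inside
the box. Each epoch is an outward and a return minimum-jerk leg
(`s(tau) = 10·tau^3 − 15·tau^4 + 6·tau^5`), so position is smooth and
velocity vanishes at every epoch boundary, and the record length is exactly
the sum of rest and reach durations. Durations are drawn uniformly from
configured intervals and rounded to whole 10 ms samples.

**Neural signals.** Each channel is 1/f (pink) background noise plus seven
band-limited Gaussian carriers, one per canonical band — a reasonable
approximation of the ECoG spectrum. The latent drive `d(t)` is the first PC
of the z-scored clean kinematics rescaled to [0, 1]. For each informative
(channel, band, gain, lag) entry the carrier amplitude is multiplied by
`max(0, 1 + gain·d(t − lag))`; an LMP entry adds `lmp_amp·gain·d(t − lag)`
microvolts. Optional 60 Hz line noise (off by default) exists to verify that
the band definitions avoid the line frequency.

**Default study conditions.** 16 channels; 45 reaches of 1.5–3.5 s separated
by 2–12 s rests (roughly seven to eight minutes, matching a single
experimental block with subject-style reach durations); pink background
RMS 55 µV; per-band carrier RMS 25 µV; three informative pairs — high
gamma 1 on channel 3 (gain +0.6, lag −100 ms), mu on channel 7 (−0.9, 0 ms)
and beta on channel 12 (−0.95, +100 ms) — i.e. one movement-activated
high-frequency site and two desynchronizing low-frequency sites, with both
motor-like (negative) and sensory-like (positive) latencies. The gains were
calibrated once, during generator design, so that end-to-end PC1 decoding
lands in the 0.5–0.8 range reported for real ECoG reach decoding at this
model size; they are a design constant of the generator, not a fit to any
particular run. Shorter reaches were preferred over longer ones because the
drive then has enough temporal structure for best-lag estimation on the
50 ms grid to be meaningful at moderate SNR.

**What the generator does not emulate.** Volume conduction and spatial
correlation between channels; non-stationary noise, artifacts (EMG, eye,
movement); cross-frequency coupling; trial-to-trial variability in neural
gain; any nonlinearity beyond the envelope clipping. Passing tests therefore
demonstrate internal consistency of the pipeline and correct recovery under
the stated encoding model — not performance on real recordings.

## Numerical and design choices

- **Filter design.** Windowed-sinc FIR via `signal::fir1` with a Hamming
  window, normalized explicitly to unit gain at the band center (DC for the
  delta low-pass); the library's own `scale = TRUE` normalization
  mis-scales a narrow low-pass.
- **Zero-phase filtering** is the literal forward-backward causal pass with
  zero initial state (FFT convolution). Its interior impulse response is
  the autocorrelation of the coefficients, which the tests verify against a
  direct convolution oracle. Whole-bank extraction shares one FFT of the
  signal across all bands and convolves with the combined kernel
  `conv(b, b)`; this equals the literal two-pass in the interior, and the
  edges where they differ lie inside the trimmed margin.
- **Correlation at a lag** uses only the overlapping samples — no padding —
  and returns r = 0 with a warning when a trace is constant within the
  overlap (detected by a relative-variance threshold, guarding against
  catastrophic cancellation as well as exact constants).
- **Degenerate designs.** Rank-deficient OLS falls back to the minimum-norm
  solution with a warning; a rank-deficient kinematic covariance warns and
  proceeds (a zero eigenvalue is legitimate for planar movement).
- **Determinism.** Sessions are bit-identical for a fixed seed; the shuffle
  null and the full pipeline are seed-reproducible.

## Problem sizes used by the test suite

The packaged checks run the full study-scale conditions where the property
being tested requires them (encoding recovery, chance separation, PC
ordering use the 16-channel, ~7.5-minute default session) and deliberately
smaller ones elsewhere: unit fixtures use 4-channel, ~40 s sessions; null
calibration uses twenty 4-channel, ~65 s unencoded sessions with
256-surrogate nulls; the significance-separation null uses 256 surrogates
rather than the canonical 1024. These sizes were chosen so the whole suite
runs comfortably on a laptop while leaving every statistical bound
meaningful at its stated level.

## Known limitations

- The decoder is linear and offline; no causal/online mode is provided.
- `permute`-mode nulls are anti-conservative for smoothed features; the
  circular-shift default is recommended and used throughout.
- With very short sessions (tens of seconds) the effective degrees of
  freedom per fold are few and fold-level r is volatile; session lengths of
  several minutes are assumed by the defaults.
- The high-gamma bands alias under the canonical pipeline order; the
  envelope is preserved, but users comparing absolute power levels across
  orders should use `envelope_first` consistently.
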