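---
title: "Holographic feature maps for EEG emotion recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holographic feature maps for EEG emotion recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`holofm` implements a complete EEG affect-recognition pipeline in which the
spatial pattern of per-channel signal characteristics is encoded as a 2-D
*holographic feature map* and classified with a CNN-plus-SVM stack, after an
explicit channel-selection stage. This vignette is the package's own account
of the science: the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic benchmark does and does not show.

## The pipeline at a glance

Each trial is a channels-by-samples matrix at 128 Hz with self-assessment
ratings of valence, arousal and dominance. The stages are:

1. **Subband decomposition.** A 4-level discrete wavelet transform with the
   db5 mother wavelet splits every channel into the five dyadic bands
   (delta 0–4, theta 4–8, alpha 8–16, beta 16–32, gamma 32–64 Hz). Features
   are computed on the time-domain reconstruction of each single coefficient
   branch (D1 → gamma … A4 → delta), not on raw coefficients, so that the
   time-domain characteristics (Hjorth, fractal dimension, peak-to-peak) are
   well defined and all five band series keep the trial's length.
2. **Signal characteristics.** Nine scalars per (channel, band): band power
   `sum(x^2)/N`; differential entropy `0.5*log(2*pi*e*sigma^2)` (nats,
   unbiased variance); Higuchi fractal dimension; Hjorth activity, mobility
   and complexity; RMS; peak-to-peak; and the mean of the Welch PSD.
3. **Holographic maps.** For a fixed (characteristic, band), the per-channel
   values become amplitudes of point sources placed at the electrodes'
   3-D positions on a unit sphere, and an off-axis hologram is rendered:
   object wave `O(u) = sum_j (a_j/r_j) exp(i 2*pi*r_j/lambda)`, tilted plane
   reference `R(u) = exp(i 2*pi*sin(theta)*u_x/lambda)`, recorded intensity
   `|O + R|^2`. Nine maps per subband, 45 per trial.
4. **Channel selection.** ReliefF (R-HOLO-FM) or diagonal-transform
   neighborhood component analysis (N-HOLO-FM) weights the flattened
   `channels x 45` feature table against the binarized labels; per-channel
   scores are the clipped sums of the channel's feature weights; the top 10
   channels are retained.
5. **Representation and classification.** One small CNN per characteristic
   (two 2x2/stride-2 convolutions with ReLU, one 2x2 max-pool, a fully
   connected feature layer with a 2-way softmax head for training) is
   trained on the selected-channel maps; the FC activations of the five
   band maps are concatenated per trial, the nine characteristic blocks are
   fused, and a polynomial-kernel SVM classifies high vs. low affect under
   stratified 10-fold cross-validation.

## The synthetic benchmark

The restricted affective-EEG corpora (DEAP, DREAMER, AMIGOS, SEED) are
registration-gated, so the package ships a generator
(`generate_synth_eeg()`) that emulates exactly the statistical structure the
method exploits: class-conditional band-limited power differences on a
subset of channels over a 1/f background.

Per channel, a trial is 1/f Gaussian noise (spectrally shaped white noise,
unit variance, slope `noise_exponent`, default 1 — the canonical EEG
background slope) plus one sinusoidal oscillation whose centre frequency is
drawn uniformly inside the informative band per trial and whose phase is
randomized per trial and channel (so no phase-locked shortcut exists). On
the informative channels the oscillation amplitude is multiplied by
`effect_size` when the trial's latent class is high; everywhere else the
amplitude is class-independent. Ratings are drawn uniformly from the
corresponding open side of the rating threshold, never exactly at it, so
binarization recovers the latent class without a tie rule. Latent classes
are balanced 50/50 per affect dimension by default, which keeps the
majority and class-ratio baselines informative.

Defaults: 40 trials (one participant's session), the 14-channel montage,
4-second trials (a common epoching window at 128 Hz), informative channels
F3/F4/T7 (frontal/temporal sites that dominate published channel-usage
surveys), gamma band, amplitude ratio 4. An amplitude ratio of 4 is a
*strong* effect (a ~16x band-power ratio); `effect_size = 1` is the null.

What the generator does **not** emulate: ocular/muscular artifacts, volume
conduction, non-stationarity, realistic cortical source geometry, or
inter-subject variability. Passing benchmarks on this data therefore
demonstrates that the pipeline's machinery is wired correctly and can
recover a known band-power effect — not that it attains any particular
accuracy on real recordings.

## Electrode geometry

The three montages (`emotiv14`, `biosemi32`, `scan62`) use idealized
10–20/10–10 positions on a unit sphere (+X right, +Y anterior, +Z apex),
generated by the classical proportional construction: the outer ring (Fpz,
T7, Oz, T8, …) at 72° inclination in 18° azimuth steps, midline electrodes
at 18° steps along the nasion–inion arc, and intermediate electrodes at
equal fractions along the transverse arcs joining midline to outer ring.
This reproduces the standard idealized cap geometry, is exactly
mirror-symmetric, and is montage-independent (shared labels share
coordinates). The 62-channel cap's two cerebellar leads CB1/CB2 are not part
of the 10–10 grid; they are placed on the sphere's equator at the azimuth of
O1/O2 — a documented package convention.

## Numerical choices

* **Wavelet boundary handling.** The transform is *periodized* (circular)
  on the orthonormal db5 basis. With kernel-orthogonal filters this makes
  analysis/synthesis an exact orthonormal expansion: the five single-branch
  reconstructions sum back to the input to machine precision, which is the
  property the feature stage relies on. Trial lengths at 128 Hz are
  dyadic-friendly; other lengths are padded circularly to the next multiple
  of 16 and cropped after reconstruction, which preserves the exact
  sum-to-input identity. Band edges are the nominal dyadic ones; the db5
  roll-off is accepted as-is, with no post-filtering.
* **Differential entropy** uses the natural logarithm (the Gaussian closed
  form is then exact) and the unbiased variance; **Hjorth activity** uses
  the `1/N` moment exactly as defined. The derivative in mobility/
  complexity is the first difference without sampling-rate scaling — both
  are ratios in which the scaling cancels.
* **Higuchi** uses `k_max = 8` by default (a common choice for 128 Hz
  windows; configurable), with the `(N-1)/(floor((N-m)/k)*k)` length
  normalization and a least-squares fit of `log <L(k)>` on `log k`.
* **Welch PSD**: 1-s Hamming segments (128 samples, the natural dyadic
  window at 128 Hz), 50% overlap, one-sided density normalization; the
  feature is the mean over all frequency bins of the already band-limited
  series. Features are computed over the whole trial, with no
  sub-windowing.
* **ReliefF** runs a deterministic full pass (every instance visited once,
  `m = n`) with `k = 10` neighbors by default; distances are
  range-normalized per feature; constant features contribute zero; classes
  smaller than `k+1` degrade `k` with a warning. The weight update
  normalizes each term by `m*k`, the canonical form of the algorithm.
* **NCA** is restricted to a diagonal transform (per-feature weights, the
  feature-selection variant), maximized by gradient ascent from the
  all-ones start with step halving on non-improving proposals — the
  accepted objective sequence is non-decreasing by construction — and
  log-sum-exp shifting of the softmax terms so large distances cannot
  underflow. Features are standardized first; returned weights are the
  squared diagonal entries. The ridge penalty defaults to `lambda = 1/n`:
  with well-separated classes the neighbor probabilities saturate and the
  unpenalized gradient vanishes, so some regularization is required for
  NCA to shrink uninformative weights at all; `1/n` keeps the penalty on
  the scale of one instance's objective contribution.
* **Channel scores** are sums of the positive parts of feature weights;
  clipping prevents harmful features from cancelling informative ones.
  Ties everywhere break lexicographically by label, making rankings fully
  reproducible.
* **Degenerate inputs.** Constant band series yield 0 for the variance-
  based features, with a counted warning; constant feature maps normalize
  to uniformly active point clouds; constant fields colorize to a single
  color; single-class label vectors are rejected outright (mirroring the
  participant exclusions customary for these corpora).
* **Hologram optics** are dimensionless and frozen: wavelength 0.5 head
  radii, a 200x200 plane spanning twice the head diameter, scene distance
  3 head radii, reference tilt 30° (carrier fringe period of ~50 pixels at
  the default resolution, far from aliasing). The feature value is encoded
  as point-source *amplitude* at the fixed electrode position: the active/
  inactive coloring of the rendered maps is exactly the amplitude contrast.
  Per-map min–max normalization to `[0.05, 1]` gives the CNN a consistent
  dynamic range. Maps can be rendered at reduced resolution for speed; the
  geometry, normalization and colormap are resolution-independent.
* **CNN defaults.** Filter counts 8/16, `d_fc = 64`, max-pool after the
  second ReLU, SGD momentum 0.9, learning rate 0.001, L2 0.04, batch 32.
  The training recipe's stated constants are fixed; the filter counts,
  feature width and epoch count are package choices kept small for CPU
  training. Each (trial, band) map is a separate training sample carrying
  the trial's label; per-trial features are the concatenated FC activations
  of the five band maps. The 2x2/stride-2 kernels make patch extraction a
  bijective reshape, so the whole network runs as dense matrix products —
  training is exactly reproducible for a fixed seed.
* **SVM**: polynomial kernel, degree 3, `C = 1`, `coef0 = 1`, standardized
  inputs (only the kernel family is prescribed; these are the package's
  frozen defaults).
* **Cross-validation** is stratified with a fixed seed; ratings binarize
  strictly above the threshold (4.5 on 1–9 scales, 2.5 on 1–5; ratings at
  the threshold are low). Channel selection runs *inside* each training
  fold by default — the leak-free reading — with
  `select_per_fold = FALSE` available to reproduce the
  once-per-participant variant. Macro-F1 is the unweighted mean of the two
  per-class F1 scores.

## Design questions that were genuinely open

* *Features on coefficients or reconstructions?* Reconstructions, so that
  time-domain features are defined and bands share the trial length; the
  alternative would shorten deeper bands dyadically.
* *How are per-feature weights turned into channels?* The clipped-sum rule
  above; selecting "channels containing top features" is order-equivalent
  when effects are strong, but the sum is stable when single features are
  noisy.
* *How do band maps enter the CNN?* As separate samples (not as extra
  image channels, not averaged): this reconciles "45 maps per trial" with
  one 3-channel image per forward pass, and leaves band identity to the
  fusion stage, which concatenates band blocks in fixed order.
* *Selection before or inside cross-validation?* Inside each fold by
  default; the alternative leaks test labels into the channel ranking and
  is provided only as an explicit flag.
* *Per-dataset channel summaries.* Cross-participant summaries are by
  counting top-10 membership across participants (`subset_participants()`
  supports cohort splits such as male/female runs); any single-participant
  ranking remains exactly reproducible.

## Benchmark sizes and what the tests compute

The shipped acceptance suite (and `scripts/acceptance.R`) uses problem
sizes chosen as the package's desk-scale benchmark: 120-trial synthetic
participants, 64x64 maps, a reduced CNN (4/8 filters, `d_fc = 16`, 6
epochs) and 10-fold CV for the end-to-end run; 10 generator seeds for the
informative-channel recovery rate; 32x32 renderings against the
literal-loop interference oracle; and the three montages for the top-10
retention percentages (10/32 = 31.25%, 10/14 = 71.43%, 10/62 = 16.13%).
On this benchmark the reduced pipeline separates the strong effect
(mean 10-fold accuracy and macro-F1 at or near 100%) and stays at chance
for the null — the two behaviors that certify the wiring end to end.

## Known limitations

* The optical constants of the holographic stage are conventions; no claim
  is made that they match any physical recording geometry, and the cited
  upstream CGH implementations may include normalizations not reproduced
  here.
* The native-R CNN is deliberately small; it is an extractor for 200x200
  (or smaller) maps, not a general deep-learning facility.
* Binarization discards rating magnitude; trials rated exactly at the
  threshold are counted low by convention.
* Nothing in the synthetic benchmark supports biological claims about
  which scalp regions matter for emotion; informative channels are wherever
  the generator put them.
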