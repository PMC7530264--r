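---
title: "From EEG signals to texture classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From EEG signals to texture classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how the pipeline works, which knobs matter, and
the choices made where the method left room for interpretation. It
states no result that the test suite does not itself compute.

```{r setup}
library(eegheatmap)
```

## The signal-to-image model

The premise: alcoholic-predisposition EEG shows elevated high-frequency
activity in a subset of fronto-central/temporal electrodes, while
control EEG in the same electrodes is dominated by low frequencies. A
recording is mapped to an image so this difference becomes *texture*:

1. keep the 11 highest-variance electrodes (FP1, FP2, F7, F8, T7, T8,
   CZ, C3, C4, CP5, CP6);
2. clip samples beyond ±73.3 µV — excursions of that size are
   head/eye-movement artifacts, not cortical signal;
3. min-max normalize to [0, 1] and quantize to 8-bit integers,
   `q(x) = floor(255 x + 0.5)`;
4. write channel *c*'s series down the rows of pixel columns
   `[32c, 32(c+1))`: 11 channels × 32 = 352 columns, 1,024 rows.

A smooth (low-frequency) channel yields long vertical runs of similar
gray — a flat block; a high-frequency channel alternates rapidly — a
rough block. Texture descriptors quantify exactly that.

Design notes on this stage:

- **Clipping vs dropping.** The published rule only says outliers are
  "removed". Clipping is the default because it preserves the fixed
  1,024-sample length the image needs; `outlier_mode = "drop"` replaces
  outliers by linear interpolation of the nearest in-range neighbors
  instead (endpoints take the nearest valid value).
- **Normalization scope.** The signals are normalized as a set, i.e.
  one min-max over all selected channels jointly, so relative channel
  amplitudes survive into the image; `normalization = "per-channel"`
  is available for sensitivity checks.
- **The 11-channel list.** The printed electrode list contains twelve
  tokens with T7 repeated; the package uses the 11 unique labels.
- **Rounding.** `floor(x·255 + 0.5)` is used rather than `round()`
  because it is platform-stable (no banker's rounding) and monotone.
- **Block filling by replication,** not interpolation: it produces the
  flat/rough bands the model relies on and is exactly invertible
  (averaging a block's columns recovers the quantized series), which
  the tests exploit.
- **Orientation.** Time runs down the rows (1,024) and channels across
  the columns (352), matching the published image geometry of
  1,024 × 32 per channel.

## Texture descriptors

**GLCM / Haralick.** `compute_glcm()` pools pair counts over the four
distance-1 directions (0°, 45°, 90°, 135°), symmetrizes and normalizes
— the method publication fixes none of these, so the common defaults
are used and all are arguments. `haralick_features()` returns the
canonical 14 statistics; entropies are in bits, gray levels are indexed
0-based, sum variance is centered on the sum average, and degenerate
denominators (zero marginal variance, zero marginal entropy, fewer than
two populated levels for the maximal correlation coefficient) return 0.
The implementation is verified against a separately written brute-force
loop implementation on random images.

**LBP.** Codes threshold P = 8 circular neighbors (bilinear
interpolation off-grid) against the center with the convention that an
exactly-equal neighbor sets its bit. The published feature count (48)
does not pin down a configuration; the package uses radii R ∈ {1, 2, 3}
with each 256-value code histogram folded into 16 equal-width bins —
3 × 16 = 48. A comparison tolerance of 1e-7 in the bit test keeps codes
stable under floating-point noise, which makes the descriptor exactly
invariant to global gray offsets (a property the tests check).

**Hu moments.** The printed normalization exponent α = (p+q)/2 is not
scale-invariant, although scale invariance is the descriptor's stated
purpose; the package defaults to the standard α = (p+q)/2 + 1 and keeps
the printed variant behind `exponent = "printed"`. The tests verify
translation/rotation invariance to 1e-8 and 2× nearest-neighbor scaling
stability to 1e-3 for the default, and demonstrate that the printed
exponent is unstable under scaling.

## Deep features

Headless extraction means: resize the image bilinearly to the
backbone's canonical input size, replicate gray to 3 channels, apply
that backbone's input scaling, run its convolutional stack, and global
average pool to a flat vector whose length is fixed by a registry of 12
architectures (MobileNet → 1,024, VGG16 → 512, ...). The backbone
itself is **injected as a callable**: the package does not depend on a
deep-learning runtime, never downloads weights, and tests the contract
(dimensions, purity, error on mismatch) with stubs — including a seeded
random-projection stand-in labelled as such. The canonical per-backbone
input sizes are used because the sizes used on the original 1,024 × 352
images were not published.

## Classifier evaluation

`evaluate()` draws 10 independent stratified 80/20 train/test splits.
Within each split, `random_search()` samples 20 hyperparameter
candidates from the printed domains and scores each by mean accuracy
over a stratified 10-fold cross-validation of the training portion; the
best is refit on the full training portion and scored on the held-out
20% with macro-averaged metrics. This reading — repeated shuffle splits
outside, k-fold CV inside the search — reconciles the "ten subsets with
a proportion of 80%/20%" protocol with its "cross-validation" label.

Domains: k-NN k ∈ odd 3..15; MLP hidden size 2..1000 (log-uniform);
SVM C = 2^e, e ∈ −5..15, γ = 2^e, e ∈ −15..3, degree ∈ odd 3..9,
kernel ∈ {linear, poly, rbf}; RF criterion ∈ {gini, entropy},
min_samples_split ∈ 2..6, min_samples_leaf ∈ 1..6, 3,000 trees; naive
Bayes has none and skips the search.

Backend notes (the module surface hides these):

- random forest runs on `ranger` (single-threaded for determinism).
  Neither `ranger` nor `randomForest` offers entropy/information-gain
  splitting, so both sampled `criterion` values execute with Gini
  impurity; the sampled value is still recorded with the chosen
  parameters. `min_samples_split` has no direct `ranger` analogue and
  is approximated through the minimum node size.
- the MLP is `nnet`'s single-hidden-layer network trained by BFGS; the
  originally named Levenberg–Marquardt trainer is not available in
  standard R stacks and a quasi-Newton optimizer is the accepted
  substitute for this model size.
- SVMs are `e1071` (libsvm); k-NN is `class::knn`. Features are
  standardized (train-set mean/sd) for the distance- and
  margin-based families; forests and naive Bayes see raw features.
- Macro averaging with a zero-division convention of 0 is used because
  it exactly reproduces the closed-form metrics of degenerate constant
  predictors (e.g. 61.11/30.56/50.00/37.93 on an 18-sample test set
  with 11 majority members), which per-positive-class metrics cannot.

## The synthetic generator

`generate_recording()` emulates exactly the statistical structure the
pipeline assumes, and nothing more:

- 64 named 10–20-system channels at 256 Hz, 1,024 samples (one image
  height, no padding);
- the 11 analysis channels carry a sum of 3 equal-amplitude sinusoids
  with random phases and frequencies drawn from the recording's DFT
  grid inside the class band — 1–7 Hz for controls, 20–50 Hz for
  alcoholic recordings. Grid frequencies keep the emitted power
  exactly inside the band (no spectral leakage), giving a clean class
  signature; a band containing no grid frequency falls back to uniform
  draws. The per-component amplitude is `band_amplitude/3`, so the
  class signal never exceeds `band_amplitude` (20 µV by default);
- all channels receive Gaussian noise (sd 5 µV, a realistic in-band
  noise floor relative to a 20 µV signal);
- each (channel, sample) cell independently becomes a ±90 µV spike
  with probability 0.001 — beyond the 73.3 µV rule by construction, so
  every artifact deterministically exercises the clipping stage.

What it deliberately does **not** model: 1/f background spectra,
event-related potentials, the stimulus paradigm, eye-blink morphology,
inter-channel correlation. Passing tests therefore demonstrate that the
pipeline recovers frequency-content class structure through the image
representation — not that it reaches any particular accuracy on
clinical recordings.

The end-to-end study in the test suite uses 30 recordings per class
with the alcoholic amplitude doubled (40 vs 20 µV), runs
preprocess → imaging → LBP → random-forest evaluation with the full
search protocol, and requires ≥ 90% mean macro accuracy, with a
label-permuted rerun required to stay within 3 sd of 50%. These problem
sizes (60 recordings of 64 × 1,024 samples) keep the whole suite
runnable on a laptop while leaving the separability margin wide.

## Numerical and degenerate-input conventions

- Constant recordings quantize to all zeros (zero range).
- Quantization is monotone; clipping is idempotent; the pipeline is
  invariant to adding a constant offset to all channels.
- Recordings longer than `time_length` are truncated; shorter ones
  error unless `pad_mode = "edge"` repeats the final sample.
- Seeds: every stochastic stage (generation, splits, search, forest)
  derives per-unit seeds from the caller's seed with fixed prime
  strides, so any subset of a dataset or any single split is
  reproducible in isolation.
- The UCI-style text reader orders channels alphabetically so that the
  assembled matrix is independent of record line order; trials are
  concatenated along time in ascending trial order, which is how a
  256 samples/s, ~1 s-epoch archive can fill a 1,024-row image.

## Known limitations

- The entropy split criterion for random forests is recorded but
  executed as Gini (backend limitation; see above).
- With per-recording joint min-max normalization, a single surviving
  extreme value scales all channels; the ±73.3 µV clip bounds this.
- LBP here is the plain code histogram — no uniform/rotation-invariant
  variants, which the original feature counts do not call for.
- How many images per subject entered the published evaluation is not
  stated; `evaluate()` treats rows as independent samples and leaves
  the subject-to-sample mapping to the caller.
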