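---
title: "Spectral band selection for hyperspectral microscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral band selection for hyperspectral microscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiband)
```

## The problem

A hyperspectral microscope records a full optical spectrum at every
spatial pixel, producing a hypercube `X` of shape y × x × λ — for the
instrument configuration this package targets, 64 × 64 spatial pixels and
λ = 1004 spectral channels covering 325–1056 nm at 0.728 nm per channel.
Most of those channels are redundant for classification: neighbouring
bands are highly correlated, and tissue types stained the same way (e.g.
H&E histology sections) have nearly identical spectra except in narrow
wavelength regions. Band *selection* — keeping a contiguous subset of
original channels, rather than transforming them as PCA-style feature
extraction does — reduces the data while preserving the physical meaning
of every retained wavelength.

`hsiband` implements a ranking-based selector: score every channel with a
simple per-band statistic, slide a fixed-width window along the spectral
axis, and keep the window with the greatest cumulative score.

## The selection criteria

All three criteria operate on the pixels-by-channels view of a cube
(`y·x` rows, λ columns). For channel λ:

* **Standard deviation (STD)** — the population spatial standard
  deviation
  σ_λ = sqrt( (1/yx) Σ_ij (X_ijλ − μ_λ)² ),
  where μ_λ is the band's spatial mean. A band where pixel intensities
  disperse widely around the mean is carrying spatial structure —
  exactly what a classifier can use. The divisor is `yx`, not `yx − 1`:
  σ_λ describes the observed image, it does not estimate a population
  parameter.
* **Mutual information (MI)** — each band and the per-pixel mean
  spectrum μ (mean over channels, one value per pixel) are discretized
  independently into B equal-width bins over their own ranges, and
  I(λ; μ) = Σ p(v,u) log₂ [ p(v,u) / (p(v)p(u)) ]
  is estimated from the joint pixel counts, in bits.
* **Shannon entropy** — the entropy H(λ) = −Σ_b p_b log₂ p_b of the
  band's own B-bin intensity histogram, in bits.

A window `W_k = [s, e)` of width `w` channels gets the cumulative score
S_k = Σ_{λ=s}^{e−1} score(λ), computed for every start position
(stride 1), and the selected window is the argmax, ties resolving to the
smallest start. The **random baseline (RBS)** draws the start uniformly
over the admissible positions; it exists to show that the structured
criteria beat chance.

Windows are half-open 0-based channel intervals throughout the API,
matching the `X[:, :, s:e]` slice notation; the wavelength window
470–570 nm on the full axis is channels `[199, 337)`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_nm` | 20 nm | Physical window width; converted to channels by rounding `width/step` to the nearest integer (20 nm → 27 channels at 0.728 nm). Widths under 20 nm are allowed but warned against: near the spectral edges instrument noise inflates every criterion, and a very narrow window can rank a noise region above a real feature. |
| `n_bins` (B) | 64 | Histogram bins for MI and entropy. With 4,096 pixels per 64×64 band, 64 bins keep ≥ 64 expected counts per occupied bin — a reasonable bias/variance point — and make degenerate constant bands explicit (single occupied bin, H = 0, I = 0). Binning is range-relative, so H and I are invariant under increasing affine rescaling of intensities. |
| `aggregation` | per-cube mean | Dataset-level selection computes one score vector per cube and averages them unweighted before the argmax, because training needs a single shared window across all cubes. Averaging (rather than pooling all pixels) keeps each cube's contribution equal regardless of its intensity scale. |

Data-size reduction is accounted spectrally: keeping `w` of `n` channels
discards `1 − w/n` of the cube (spatial extents never change). A 27-channel
window on 1004 channels discards 97.3%.

```{r}
w <- nm_width_to_channels(20, 0.728)
c(channels = w, reduction = round(100 * reduction_fraction(w, 1004), 1))
```

## The synthetic data generator

Real stained-tissue hypercube collections are rarely shareable, so the
package ships a simulator whose outputs exercise every downstream stage
with a known ground truth:

* **Class signatures.** All classes share one smooth polynomial baseline;
  each non-background class gets two Gaussian peaks whose centers lie
  strictly inside a configurable *informative window* (margin 20% of the
  window width, peak sd = width/12). Outside the window the pairwise
  class differences are tail-only, below 10% of the in-window contrast —
  emulating organ tissues with high spectral similarity everywhere except
  one high-variance region. At the full 11-class design the last class is
  a peak-free background.
* **Spatial texture.** Each cube multiplies its signature by
  `A(i,j) = 1 + texture_amp · field`, where `field` is a smoothed,
  re-standardized Gaussian random field (correlation length
  `texture_scale` pixels). Multiplicative texture mimics stain-density
  variation and gives a closed form: with zero noise,
  σ_λ = sd(A) · signature(λ) exactly, which the tests verify to
  ~1e−16 relative error. Additive structure would not give this oracle.
* **Noise.** Per-voxel Gaussian noise whose scale ramps linearly from
  `base_sigma` up to `edge_factor × base_sigma` over the last
  `edge_width_nm` nanometres at either spectral end — the qualitative
  edge-noise behaviour of slit-spectrograph systems, and the reason the
  20 nm window floor exists. The exact noise law of any real instrument
  is unknowable from summary descriptions; a linear ramp is the simplest
  shape with the right monotonicity.

Defaults (chosen once, as plausible for H&E microscopy at unit-scale
reflectance): peak amplitude 0.5, `texture_amp` 0.2, `base_sigma` 0.02
(signal-to-noise 25 at the peaks), `edge_factor` 4, `edge_width_nm` 40.
Two profiles exist: `"paper"` (11 classes × 100 cubes, 64×64×1004,
informative window 470–570 nm) matches the full study design; `"test"`
(5 × 10, 32×32×200, window 360–390 nm — the analogous interior position
on the shorter axis) is the desk-scale benchmark used by the test suite,
keeping the default test run in minutes.

What passing tests on this simulator do **not** show: performance on real
tissue. The generator has no chromatic aberration, no scan-line
artifacts, no spatially structured noise, no class-conditional texture
statistics, and its class differences are by construction confined to the
planted window. Results on it validate the *machinery* (scoring, window
optimization, training protocol) and directional claims (structured
selection beats chance), not absolute accuracies.

## The classifier harness

The CNN is deliberately minimal: two 3×3 same-padded convolutions
(default 16 and 32 filters — the filter counts are a free choice, the
smallest common doubling scheme), each followed by ReLU and 2×2/stride-2
max pooling, then a 512-unit ReLU layer and a linear output per class.
Spectral channels enter as input feature channels, so narrowing
1004 → 27 channels changes only the first convolution's input arithmetic;
every downstream shape is untouched. The implementation is vectorized
base R (im2col patch matrices multiplied through BLAS, with exact
backprop verified against finite differences in the tests).

Training follows the standard small-data protocol: cross-entropy, Adam
from `lr_init = 1e-4` with multiplicative per-epoch decay (factor 0.95 —
a schedule has to be chosen; exponential is the least structured),
batch size 2, early stopping after 15 epochs without validation-loss
improvement. The split is stratified 80/20 train/test per class (11 × 100
cubes → exactly 880/220); a 10% validation subset is carved *from the
training portion* rather than validating on the test set, which costs a
little training data but keeps the early-stopping signal leak-free.
Inputs are min–max normalized to [0, 1] with the range fitted on the
non-test portion only. Window selection likewise runs on the non-test
cubes only; a test asserts the selected window is reproducible from the
train+validation subset alone.

Both the best-validation-epoch and final-epoch test accuracies are
recorded (`accuracy`, `accuracy_final`); summaries use the best-epoch
value.

## The benchmark protocol

`run_comparison()` repeats, for each method and `n_runs` seeds
(seed + 0, 1, …): split → select on non-test cubes → slice → normalize →
train → evaluate, and reports mean ± sd accuracy over exactly `n_runs`
runs. Epoch wall-times are recorded for information only — they are
host-dependent and are written to a separate `timings.csv` so the
scientific CSVs stay byte-reproducible.

The package's own scaled benchmark (used by the test suite and
`scripts/acceptance.R`) runs the `"test"` profile with `lr_init = 1e-3`,
`max_epochs = 12`, `patience = 5`, 10 seeds. The higher learning rate and
short epoch budget fit the small problem: ~500 optimization steps
suffice to separate the planted classes, and the comparison needs only
the *ordering* (STD mean accuracy ≥ RBS, STD sd < RBS sd), which mirrors
the stability gap between systematic and random selection at full scale.
On this benchmark STD selection recovers the planted window essentially
always, while a random window misses it in roughly 60% of draws and then
scores near chance — hence RBS's large run-to-run spread.

## Numerical choices and degenerate inputs

* Cumulative window scores use a prefix-sum difference; scores are O(1)
  per channel and axes are ≤ a few thousand channels, so cancellation is
  far below the 1e−10 oracle-agreement tolerance enforced in the tests.
* Argmax ties (exactly equal window sums) take the smallest start —
  deterministic and order-independent.
* A constant band: σ = 0, H = 0, I = 0 — scores, never errors. Empty
  histogram bins contribute 0 (the p log p limit).
* Non-finite cube values are rejected at construction and at load; the
  intended regime is raw, un-preprocessed data, so nothing is imputed or
  smoothed.
* nm → channel conversions: window *widths* round half away from zero
  (20 nm / 0.728 nm = 27.47 → 27 channels); wavelength *intervals* use
  floor/ceiling so the channel interval covers the requested range
  (470–570 nm → [199, 337)).
* The wavelength span is `n_channels × step_nm` (each channel one
  resolution element): 1004 × 0.728 = 730.9 ≈ 731 nm.
* ENVI I/O is BSQ, little-endian, float32 (type 4, the common default;
  lossless float64 available) with a mandatory `wavelength` list on a
  uniform grid; the single-file container round-trips bit-exactly.

## Known limitations

* One contiguous window only; disjoint multi-window band subsets are out
  of scope by design.
* The MI reference is the per-pixel mean spectrum — an unsupervised
  relevance proxy; no label-aware (mRMR-style) selection is provided.
* Absolute classification accuracies on the synthetic benchmark
  saturate near 100% and say nothing about real-tissue accuracy; only
  orderings and stability are meaningful there.
* The CNN harness is CPU-oriented and sized for cubes of this study's
  scale (tens of channels after selection, ≤ 64×64 spatial); it is an
  evaluation harness, not a general deep-learning framework.
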