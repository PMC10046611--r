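---
title: "Classifying microsatellite instability from Raman spectra: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying microsatellite instability from Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmsi)
```

## The problem

Mismatch-repair deficiency in colorectal cancer manifests as high-level
microsatellite instability (MSI-H), a biomarker that guides Lynch-syndrome
screening and immunotherapy decisions, yet universal testing is not met in
practice. Point Raman spectra of tissue sections offer a label-free
molecular fingerprint from which MSI status might be read directly. The
resulting statistical task is the one this package implements end to end:
given collections of point spectra (wavenumber in cm^-1 versus photon
counts), grouped by tissue sample and labelled normal, MSS or MSI-H, train
and honestly evaluate classifiers that predict the *sample's* class.

Real tissue datasets of this kind are small (tens of samples) and not
publicly deposited, so the package ships a synthetic-data module that
emulates the study design the pipeline assumes — 3 classes x 10 samples x
50 spectra (one sample with 40; 1490 spectra in total) on a 0-2100 cm^-1
axis — and every downstream stage is developed and tested against it.

## The synthetic generator

Each class is described by a `spectral_profile()`: a set of Raman bands
(Lorentzian by default, the conventional lineshape for Raman transitions;
Gaussian available) on a smooth fluorescence baseline, here a low-order
polynomial in the scaled wavenumber. The three default profiles share every
band — tissue spectra of different disease classes are known to be almost
identical — and differ only through small amplitude offsets concentrated at
680–710, 787, 800–830 and 870–900 cm^-1, the nucleic-acid- and
collagen-associated regions where MSS and MSI-H tissue plausibly differ.
The NORMAL-versus-cancer offsets are roughly three times the
MSS-versus-MSI-H offsets, encoding the expectation that separating the two
adenocarcinoma phenotypes is the hard part of the task.

Generation proceeds per sample: the baseline coefficients and an overall
amplitude factor are jittered by multiplicative log-normal draws
(`sample_sd`, default 0.05) modelling biological and sectioning variation
between samples; each spectrum receives its own log-normal factor
(`spectrum_sd`, default 0.02) modelling focus and positioning variation;
the clean band + baseline sum is rescaled to an expected total of
`mean_total_counts` photons (default 5 x 10^5, which makes shot noise
visible but small next to the class signal); and each channel is drawn
from a Poisson distribution with that expectation. The variance-component values
are a modelling choice — no empirical variance decomposition exists for
this design — and they are deliberately conservative: the class signal is
subtle relative to between-sample variation, as in real tissue.

What the generator does *not* emulate: cosmic rays, detector saturation,
substrate effects, wavenumber-dependent instrument response, or any real
biochemistry beyond band positions. Tests passing on synthetic data
therefore demonstrate that the *pipeline machinery* is correct (no leakage,
correct contracts, recoverable planted signal), not that any particular
accuracy is attainable on real tissue.

## Preprocessing

Two fixed steps, in a fixed order: truncation to the closed 400–1800 cm^-1
fingerprint window, then per-spectrum standard normal variate (SNV)
normalization to zero mean and unit variance. The SNV divisor is the
population (divide-by-n) standard deviation, so the normalized vector
itself has exactly unit variance. Truncation precedes SNV so that the
normalization statistics reflect only the modelled channels. No baseline
correction is applied anywhere; the classifiers see the fluorescence
background and must learn around it, and the difference spectra retain
their interpretable raw shape.

## Fold-internal augmentation

Training partitions (and only training partitions — copies carry a stage
marker and the validation layer refuses marked spectra in test folds) are
expanded 8x: each original spectrum is kept and 7 perturbed copies are
added. A copy is made by (1) Poisson shot noise applied to the *raw*
pre-normalization intensities — each channel becomes a Poisson draw with
the channel's (rescaled) intensity as mean, an unbiased perturbation with
variance `intensity / poisson_rescale` — and (2) a wavenumber shift drawn
uniformly from [-6, +6] cm^-1, realised by linear interpolation back onto
the fixed axis with nearest-edge padding. SNV is re-applied after
perturbation, honouring the physical order noise -> normalization. The
uniform shift distribution and the keep-the-original convention are design
choices; only the +/-6 cm^-1 bound and the 8x factor are fixed by the
protocol the pipeline reproduces.

## The three model families

All families implement one contract: `fit_model(spec, train, seed)` and
`predict_proba(model, spectra)` returning class-probability rows over a
fixed class order (for the two-class task the first column is MSS, so a
probability of 1 means MSS and 0 means MSI-H).

* **PCA–LDA** — principal components of the training spectra (components
  fitted on the training fold only), then linear discriminant analysis on
  the scores. The number of components is the tuned hyperparameter.
* **SVM (RBF)** — a radial-basis-function support vector machine with
  probability outputs via the standard parametric (sigmoid) calibration on
  training folds.
* **1D CNN** — three valid-convolution blocks (kernel sizes 9/7/5, channels
  8/16/32, ReLU, max-pool 2 after the first two blocks), flattened into a
  dense softmax head, trained with Adam on the cross-entropy. The network
  is implemented natively in R with vectorised matrix products and exact
  analytic gradients (verified against finite differences in the test
  suite), which keeps the package dependency-light and every training step
  reproducible from a seed.

One architectural choice deserves a note. A global-average-pooling head —
common in image CNNs — makes the network largely position-invariant. For
spectra this is the wrong invariance: class-differential Raman bands are
identical in *shape* and differ in *position* on the wavenumber axis, and
in development a pooled head demonstrably failed to separate classes that
differ only by band location. The flattened head preserves position and is
the default; all architectural knobs (channel widths, kernel sizes,
dropout, epochs, batch size, learning rate) live in `model_spec()` so the
inner CV loop can tune them.

## Validation protocol

Evaluation is a repeated nested cross-validation with three non-negotiable
properties:

1. **Sample-grouped splits.** All spectra of a sample travel together;
   a sample never contributes to both sides of any split, at either CV
   level. Splits are class-stratified.
2. **Fold-internal tuning and augmentation.** Hyperparameters are selected
   in a 3-fold inner CV run on the outer-training partition only,
   minimising mean spectrum-level log loss (a proper scoring rule);
   augmentation happens inside each training split, after splitting.
3. **Sample-level reporting.** Each held-out sample receives the mean of
   its spectra's probability vectors and a majority-vote label (two-class
   votes threshold the MSS probability at 0.5; ties at either the spectrum
   or the sample level resolve to the clinically worst class, by default
   MSI-H before MSS before NORMAL, because a missed MSI-H forfeits the
   Lynch-syndrome follow-up cascade).

The default 3 outer folds x 5 repeats yield 15 fold estimates per model;
repeats derive their own seeds from the base seed so the full run is
reproducible while repeats differ. Reported metrics are unweighted mean
+/- SD across folds — SDs are descriptive only, since overlapping folds
violate the independence needed for confidence intervals. Two-class runs
report sensitivity (true MSS detected), specificity (true MSI-H detected)
and AUROC over sample-level MSS probabilities, with ROC curves averaged
vertically on a fixed false-positive grid; three-class runs report
accuracy, sample-level log loss (probabilities clipped to [1e-15, 1-1e-15])
and pooled row-normalised confusion matrices.

Two levels of log loss appear deliberately: *selection* uses spectrum-level
log loss (more data per inner fold), *reporting* uses sample-level log loss
on the per-sample mean probability vectors. Mean aggregation of spectrum
probabilities into a sample probability is itself a design choice; it is
the natural continuous counterpart of majority voting and is required for
sample-level AUROC.

## Interpretation

`class_mean()` and `difference_spectrum()` expose the subtle compositional
differences between classes; `annotate_peaks()` matches local extrema of
the absolute difference against a built-in fingerprint-region assignment
table (match tolerance 5 cm^-1; unmatched peaks are reported unassigned).
`occlusion_study()` probes a fitted model directly: overlapping windows
(default 30 cm^-1 wide, 10 cm^-1 stride — comparable to a Raman band
width) are replaced by 0, the post-SNV mean and hence the least
informative value, and the drop in true-class probability is averaged over
spectra. Windows with large positive deltas are the regions the model
relies on; on synthetic data with a single planted differential band the
top-ranked window overlaps that band essentially always, which is the
package's calibration that the probe localises correctly.

## Numerical choices and degenerate inputs

* SNV refuses (numerically) constant spectra — variance at or below
  `variance_floor` (default 1e-10) — naming the offending spectrum.
* Truncation is a pure channel selection on a closed interval; an empty
  window is an error, not an empty spectrum.
* Poisson perturbation requires raw-stage, non-negative intensities.
* Inner-CV grid points that fail to fit on every inner fold are excluded
  with a warning; ties in inner log loss break deterministically by grid
  order.
* Folds whose test partition contains a single class have undefined AUROC;
  they are excluded from the AUROC summary with a warning.
* All randomness flows from named substreams of one base seed (simulation,
  outer splits, inner splits, augmentation, model fits), so any single
  fold is replayable in isolation.

## Problem sizes in the tests

The test and acceptance runs use the full 0–2100 cm^-1 range at 4 cm^-1
spacing with 6 samples per class and 6 spectra per sample (strong-signal
runs), 32 samples per class with 4 spectra each (permutation control), and
the full default 1490-spectrum design where only generation and
preprocessing are exercised. These sizes are the package's own choice of
smallest designs that still make the statistical assertions sharp: planted
signal recovered at >= 95% sample accuracy by every family, permuted-label
AUROC concentrated near 1/2, and occlusion localisation in 20 of 20
replicates.

## Known limitations

The generator's variance components are qualitative, not fitted to tissue
data; the band amplitudes are plausible rather than measured; and the
pipeline's performance numbers on synthetic data say nothing quantitative
about tissue. The CNN is intentionally small and CPU-bound; it is suited
to the few-thousand-spectrum regime this design targets, not to large
hyperspectral images. Formal inference across folds (confidence intervals,
hypothesis tests) is deliberately out of scope, as is any baseline
correction or threshold calibration study.
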