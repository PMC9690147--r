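---
title: "Reconstruction features for EEG seizure-state detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction features for EEG seizure-state detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

Epileptic EEG classification usually proceeds by engineering features —
spectral bands, wavelet coefficients, entropies — and feeding them to a
classifier. `eegrecon` implements a different, deliberately lightweight
idea: train a 1-D convolutional autoencoder on recordings from **one**
brain state only (the interictal state, i.e. between seizures), and then
describe every recording, of any state, by how faithfully that model
reconstructs it. A model that has only ever seen interictal signals
reproduces held-out interictal signals well and reproduces healthy and
ictal (during-seizure) signals poorly, so three scalar indicators of
reconstruction fidelity become a three-dimensional feature space in which
the classes separate.

For a signal $x$ of length $n$ and its reconstruction $\hat{x}$:

* mean squared error
  $\mathrm{MSE} = \frac{1}{n}\sum_{i=1}^{n}(x_i-\hat{x}_i)^2$,
* the original-to-reconstructed signal ratio, an energy ratio in decibels
  in the style of an SNR,
  $\mathrm{ORSR} = 10\log_{10}\left(\sum_i x_i^2 \big/ \sum_i \hat{x}_i^2\right)$,
* cosine similarity
  $\mathrm{CS} = \sum_i x_i\hat{x}_i \big/
  \left(\sqrt{\sum_i x_i^2}\sqrt{\sum_i \hat{x}_i^2}\right)$.

A perfect reconstruction gives exactly $(0, 0\,\mathrm{dB}, 1)$. Higher CS
means *more* similar; reference-class records therefore sit at low MSE,
ORSR near 0 dB and CS near 1, and off-class records drift away from that
corner. The triple is computed in the normalized $[0,1]$ amplitude space
the autoencoder operates in, not on raw microvolt amplitudes, and no
feature scaling is applied before the tree ensembles (trees are
scale-invariant).

The three-feature table feeds three ensemble classifiers — random forest,
multiclass AdaBoost (SAMME over decision stumps) and gradient boosting —
under a stratified 75/25 train/test split. A PCA baseline (10 components
fitted on the pooled normalized signals of all classes) provides the
comparison feature set; note the deliberate asymmetry that the
autoencoder sees only the reference class while PCA sees everything. For
interpretability, the package computes permutation importance (mean
accuracy drop over repeated column shuffles) and *exact* interventional
Shapley values — with only three features the $2^3$ coalitions are
enumerated outright, so there is no sampling approximation and the
efficiency axiom holds to numerical precision.

## Data model and input format

Recordings are single-channel, fixed-length vectors. The reader ingests
the plain-text dialect used by the University of Bonn corpus (one ASCII
sample per line, one directory per class; sets A, D and E are the
healthy, interictal and ictal classes, 100 recordings each, 4097 samples
at 173.61 Hz). Each record is trimmed to a working length of 4096
samples — the strided convolutions halve the length three times, so the
length must be divisible by 8, and dropping one sample (~5.8 ms) is
negligible — and min-max normalized to $[0,1]$ per record. Per-record
normalization (rather than global) makes every signal occupy the full
unit interval regardless of recording gain; it also means absolute
amplitude is *not* available to the classifiers, which keeps the method
honest about what reconstruction divergence alone can do. Files are read
in lexicographic order so datasets, splits and all downstream results are
reproducible. The sampling rate is carried as metadata only; nothing
downstream depends on it.

## The autoencoder

The model is a mirror-symmetric stack: three strided convolution layers
E1–E3 (each convolution + ReLU), then three transposed-convolution layers
D1–D3, with a logistic sigmoid on the output so reconstructions stay in
$[0,1]$. Training minimizes mean squared reconstruction error with Adam
at learning rate 0.001.

The stack shape (three encoder, three decoder layers) is fixed; the layer
dimensions are this package's own design choice, and they matter:

* **Channels 16/8/4, a compressing pyramid.** With stride 2 per layer the
  latent sequence is 8× shorter than the input, so 4 bottleneck channels
  give a code half the size of the input. A widening stack (e.g.
  16/32/64) would make the latent space 8× *larger* than the input, and
  the model drifts toward an identity map that reconstructs every class
  well, destroying the one-class specificity the features depend on. A
  genuinely compressive code forces the model to commit to the reference
  class's structure.
* **Kernel 21** (~120 ms at 173.61 Hz). Longer kernels give the learned
  filters sharper frequency selectivity. The two off-classes differ
  mainly in dominant rhythm (a ~4 Hz high-amplitude discharge versus an
  8–12 Hz moderate rhythm); frequency-selective filters respond to them
  differently and systematically, which stabilizes the healthy/ictal
  contrast across training runs. With 7-tap kernels the contrast exists
  but fluctuates from seed to seed.
* **400 epochs, batch size 4.** At 200 epochs the training loss on ~100
  reference records is still visibly decreasing and run-to-run variance
  in the downstream accuracy is noticeable; doubling the epochs and
  shrinking the batch (more Adam updates per epoch) brings training to a
  plateau and makes the end-to-end result stable across seeds. Training
  stays under a few minutes on one CPU core.

Weights are initialized fan-in-scaled uniform from a seeded RNG;
minibatch order is reshuffled each epoch from the same seed, so training
is bit-reproducible. Inference is deterministic. Checkpoints are a single
JSON archive (format tag, config, full-precision weights); save + load
reproduces reconstructions bit for bit. The numerical core runs in single
precision (as deep-learning frameworks do) with im2col + BLAS matrix
multiplies; transposed convolutions reuse the convolution primitives
through the adjoint relationship, and the backward pass is verified
against finite differences in the test suite's development history.

One protocol rule is enforced rather than assumed: `train_autoencoder()`
refuses mixed-label training data. One-class training *is* the method; a
mixed training set would silently turn the features into noise.

## The synthetic generator

Real Bonn data must be downloaded by the user, so the package ships a
three-class synthetic EEG generator that reproduces the *statistical
contrast the method exploits*, not the electrophysiology:

* **healthy** — a moderate 8–12 Hz rhythm (amplitude 0.5, frequency drawn
  per record) over a pink-ish $1/f$-weighted background (amplitude 0.3);
* **interictal** — the same background with sparse epileptiform
  transients: Poisson-timed (0.8 events/s) biphasic 60 ms spikes of
  amplitude 2.0, mostly one polarity;
* **ictal** — a high-amplitude (3.0) 4 Hz discharge with a slowly varying
  ±20% envelope.

All classes add white Gaussian noise (sd 0.1) and are min-max normalized
per record, exactly like loaded data. The defaults (100 records per
class, 4096 samples, 173.61 Hz) mirror the size and format of the real
corpus. Each record derives its own RNG substream from the master seed
and a counter, so any single record is reproducible in isolation. A
`"reduced"` contrast preset — spikes 2.0→0.8, discharge 3.0→1.0, healthy
rhythm 0.5→0.35, noise 0.1→0.2 — gives a deliberately harder problem used
to compare feature extractors under stress.

What the generator does *not* emulate: true EEG spectra and nonstationarity,
artifacts (eye blinks, muscle), inter-patient variability, multichannel
structure. Passing end-to-end tests on synthetic data therefore
demonstrates that the pipeline's machinery — one-class training,
reconstruction divergence, classification, attribution — behaves as
designed on data with the intended class structure; it does not certify
clinical performance. Evaluating on the real corpus requires the download
(see the README).

On synthetic data the PCA baseline is, if anything, *stronger* than on
real EEG: after per-record normalization the synthetic classes still
differ in how variance distributes across low-frequency components, which
tree ensembles can exploit from raw PC scores. The package therefore
makes no claim that reconstruction features beat PCA at every setting of
the generator; the stress comparison in the test suite uses the
reduced-contrast preset, where spike- and rhythm-driven structure is
weak.

## Numerical and protocol choices

* CS is standard cosine similarity — higher means more similar — and the
  ORSR energy sums run over all $n$ samples. CS is clamped into
  $[-1, 1]$ against floating-point overshoot; MSE/ORSR raise errors on
  zero-energy inputs rather than returning infinities.
* The train/test split is stratified by class — a plain random split
  would leave per-class test counts uneven — and both feature sets share
  the same record partition, so the comparison is paired.
* Classifier hyperparameters default to common values (100 trees
  everywhere; unlimited-depth forest; gradient
  boosting depth 3, learning rate 0.1), all overridable. AdaBoost uses
  SAMME over depth-3 trees rather than classic stumps: with three classes
  the base learner must beat error 2/3, and on a 3-dimensional feature
  space depth-1 stumps cannot express the feature conjunctions that
  separate overlapping classes, which makes stump-SAMME collapse exactly
  where the comparison is interesting. Voting ties break toward the
  lowest class index for determinism.
* The classifiers consume all 10 PC scores; the 3-component min-max view
  (`normalize_pcs()`) exists for plotting only. Both counts are
  configuration keys.
* The Shapley background set is the training split, subsampled to at most
  100 rows with a fixed seed — the standard interventional baseline. The
  published single-bar-per-feature SHAP summary corresponds to the
  class-averaged mean $|\phi|$ reported by `shapley_importance()`.
* The master seed fans out to stage seeds by fixed offsets (data +0,
  autoencoder +1, split +2, classifiers +3, interpretability +4); the
  whole pipeline is byte-reproducible from (config, seed), which the test
  suite asserts on serialized JSON reports.

## Problem sizes used by the automated suite

Unit tests run on shortened signals (512 samples, small channel counts,
tens of epochs) to exercise contracts quickly. The end-to-end suite runs
the genuine study scale — 100 records per class at 4096 samples, the
default 400-epoch autoencoder, all three classifiers, exact Shapley on
the held-out split — once, and shares that fitted pipeline across its
assertions. The specificity property is additionally exercised at 200
epochs with a 75-record training subset and 25 held-out records per
class.

## Limitations

* Single-channel, fixed-length, whole-record classification; no
  windowing, no streaming, no EDF/multichannel input.
* The three features summarize reconstruction divergence globally; two
  signals can in principle diverge by the same amount in different ways.
  Frequency-resolved divergence is out of scope.
* Exact Shapley enumeration is limited to ≤ 10 features by design; the
  intended use is the 3-feature reconstruction representation.
* Synthetic results validate mechanism, not clinical accuracy (see
  above).
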