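---
title: "Multimodal feature fusion for knee MRI injury classification"
author: "kneefusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal feature fusion for knee MRI injury classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Anterior cruciate ligament (ACL) and meniscus tears are the most common
knee injuries. On T2-weighted MRI the intact ligament is a dark
(low-signal) band; a tear appears as a focal high-signal interruption of
that band, and a torn meniscus as a bright line crossing the dark
meniscal wedge. Radiologists grade ACL damage on a four-level scale
(grade 0 normal, I partial damage under 50%, II damage of 50% or more,
III complete rupture), with arthroscopy as the surgical gold standard.

`kneefusion` implements a multimodal fusion classifier for this setting:
a frozen convolutional backbone with top-down feature-pyramid fusion
produces a deep feature vector, a set of handcrafted image statistics
provides a second "traditional" modality, and an energy-based model (a
restricted Boltzmann machine, RBM) fuses the two before a logistic
output unit thresholded at 0.5 makes the binary call. Because no patient
images are available, the package ships a seeded phantom generator that
emulates the qualitative MRI appearance, and the whole pipeline is
validated on phantoms plus brute-force numerical oracles. The
grade-concordance statistics (chi-square on a two-modality grade table,
sensitivity/specificity/accuracy of an index test against a reference,
concomitant-injury positive rates) operate on published count tables and
are exact.

## The phantom generator

`phantomConfig()` / `generateDataset()` draw labeled 2-D slices on a
[0, 1] intensity scale:

* background soft tissue at 0.60; ligament band at 0.15; meniscus at 0.20;
* **sagittal**: a diagonal ligament band plus a meniscal wedge near the
  tibial plateau; **coronal**: a vertical band plus the wedge;
  **transverse**: no band, but a ligament cross-section disc and a
  dominant C-shaped meniscus ring;
* an ACL tear raises a contiguous segment of the band by
  `lesionContrast` (default 0.4) before noise; a meniscus tear is a
  bright line crossing the wedge (or a radial sector of the ring);
* band position, lesion position and (transverse) tear angle jitter per
  image; labels are independent Bernoulli draws at the configured
  probabilities;
* additive Gaussian noise (default sd 0.1), clipped to [0, 1]; a Rician
  mode (`noiseModel = "rician"`) forms the magnitude of the
  complex-noise-corrupted signal instead.

The defaults — 64 px slices, tear probability 0.5, contrast 0.4, noise
sd 0.1 — are the study conditions for the end-to-end experiment; 0.4
contrast over a 0.15 band with 0.1 noise makes the lesion clearly
visible but not trivially so (the lesion intensity, 0.55, is close to
the 0.60 background, so detection requires the *geometry* of the gap,
not a histogram shift). Lesion region masks are retained on the objects
(also for negatives, where the lesion was *not* applied), so the
generator's contrast calibration can be audited by measuring region
means.

What the phantom does **not** emulate: partial-volume effects, coil
inhomogeneity, anatomical variability beyond jitter, 3-D continuity
across slices, graded (I/II) damage — labels are binary tear/no-tear.
Passing tests on phantoms therefore demonstrate that the pipeline works
as specified, not that it reaches any particular accuracy on clinical
images.

Datasets round-trip through a directory of 8-bit grayscale PNGs plus a
CSV manifest (`file, plane, acl_tear, meniscus_tear`); PNG quantizes
intensities to 1/255. For exact round trips the NIfTI mode stores
float64 volumes — lossless at the cost of size, which is the package's
deliberate reading of "higher-precision interchange".

## Backbone and pyramid fusion

The backbone is five 3x3 convolution + ReLU blocks; blocks 2-5 end in a
2x2 max pool, so the block-g map has spatial side `inputSize / 2^(g-1)`
(224 gives 112, 56, 28, 14 for blocks 2-5). Feature maps are taken
*after* each block's pooling, matching that halving sequence. The
default block range is 2..5, mirroring transfer-learning practice of
dropping the earliest block; it is configurable.

Weights are **frozen**: `weightsMode = "seeded_random"` draws He-scaled
Gaussians with zero biases from a fixed seed, giving a deterministic
random convolutional feature extractor with no download or training.
Checkpoint loading is available for externally trained weights. Nothing
downstream ever updates these parameters.

Top-down fusion walks the pyramid from the coarsest level: the running
fused map is 2x nearest-neighbour upsampled, added pixelwise to a
lateral 2x2 convolution of the raw map one level below, and the sum is
smoothed by a 5x5 convolution to suppress upsampling aliasing. The top
level's fused map is just its lateral convolution. Two numerical
choices make the pixelwise sum well defined:

* the even 2x2 kernel uses asymmetric zero padding (one pixel at the
  bottom/right), preserving spatial size;
* the 5x5 kernel uses symmetric padding 2.

Nearest-neighbour upsampling was chosen because it is exactly invertible
for the x2 case, which keeps the brute-force oracle comparisons exact.
With power-of-two inputs the upsampled and lateral maps always agree in
size; odd sizes are reconciled by at most one pixel of zero padding or
cropping (logged), anything larger is an internal error. All levels are
mapped to a common channel width (`fusedChannels`) by the lateral
convolution, since the summation requires equal channel counts.

## From fused map to feature vectors

The finest fused map passes through:

1. **Batch normalization** — per channel, statistics over all images and
   spatial positions of the batch: `scale * (x - mean) / sqrt(var + eps)
   + shift` with the *biased* batch variance in train mode and running
   estimates in eval mode (`eps = 1e-5`, momentum 0.1). The first
   train-mode batch initializes the running moments directly.
2. **ReLU**.
3. **Adaptive max pooling** to a fixed side (default 4):
   `stride = floor(In/Out)`, `kernel = In - (Out-1)*stride`, padding 0 —
   the output side is exactly `Out` for any input.
4. A frozen affine projection (the fully connected layer, equivalently a
   full-size convolution) + ReLU to the deep dimension.

The deep dimension defaults to **1026** — the method's stated width,
kept literally even though it is suspiciously close to 1024; it is
configurable, and desk-scale experiments use 128.

The **traditional modality** is 32 named statistics: intensity moments
and quantiles, 32-bin histogram entropy/energy/mode, finite-difference
gradient statistics, 8-level gray-level co-occurrence texture (contrast,
homogeneity, energy, correlation, entropy), and region-shape statistics
of the dark (< 0.35) region including the thinnest-point ratio of its
row/column profiles, which responds to a focal bright gap in a dark
band. A constant image takes the zero convention for all dispersion,
entropy and texture features. This feature set is a documented,
replaceable default: the underlying method requires *a* traditional
modality without defining one, so no claim is made that results
depending on it match any external reference.

Both modalities are concatenated as `m = (c, o)` and min-max scaled to
[0, 1] **with parameters fitted on the training set only**; held-out
values outside the training range are clipped. The no-leakage property
is asserted by recomputation in the test suite.

## Energy-based fusion

The fusion layer is an RBM over the scaled feature vector (visible
layer) with a hidden layer narrower than the visible one:

* forward pass `p_e = sigmoid(sum_i m_i theta_ie + beta_e)`;
* energy `E(x, y) = -t.x - beta.y - x' Theta y`;
* marginal `p(x) = Z^-1 sum_y exp(-E)`, with
  `Z = sum_{x,y} exp(-E)`; for 20 or fewer total units the package
  enumerates these exactly (and uses the analytic hidden-summed product
  form for log-likelihoods, with natural logarithms).

The published formulation writes the visible bias *inside* the forward
input and the interaction term; that makes the bias act twice and is
dimensionally inconsistent with the likelihood objective, so the
standard RBM forms above are the implementation and the printed variants
are kept behind `variant = "printed"` for comparison only.

Training is two-phase, fully seeded:

1. **Unsupervised contrastive divergence** (CD-k, default k = 1,
   learning rate 0.05, minibatch 16, 50 epochs) ascending the marginal
   log-likelihood of the feature vectors. Real-valued features in [0, 1]
   are treated as Bernoulli expectations: hidden units are sampled,
   visible reconstructions stay mean-field. Class labels play no role in
   this phase. When the visible layer is small enough to enumerate, the
   exact log-likelihood is logged per epoch, which is how the
   likelihood-ascent and generator-recovery properties are tested.
2. **Supervised head**: a logistic unit on the hidden probabilities,
   fitted by cross-entropy — i.e. binomial maximum likelihood, solved
   with iteratively reweighted least squares (`stats::glm.fit`), which
   is deterministic and converges where plain gradient steps underfit.

Prediction applies the sigmoid output `W` and calls positive when
`W >= 0.5`; the boundary itself counts as positive.

## Metrics and clinical statistics

`confusionCounts` / `accuracy` / `recall` / `sensitivity` /
`specificity` use the standard definitions; a zero denominator yields a
flagged `NA`, never an exception. (The source prose definitions of
FP/FN contradict themselves; only the standard definitions are
consistent with the accuracy formula.) `rocAuc` integrates the empirical
ROC by the trapezoidal rule, which equals pair-counting
`P(score+ > score-) + 0.5 P(tie)`; the value is not clamped to
[0.5, 1] — a worse-than-chance ranker scores below 0.5.

`chiSquareTest` is the uncorrected Pearson statistic (Yates correction
available behind a flag but off by default, since the baseline method
names only "the chi-square test"). `diagnosticStats` binarizes grades
with grade 0 as the sole negative class. `positiveRates` computes
per-group positive proportions and the 2x2 chi-square association
p-value. Two published inconsistencies are deliberately *not* asserted
anywhere: the printed sensitivity/specificity/accuracy triplet
(96.78/90.62/92.17%) is not derivable from the printed grade counts, and
the claimed acute-vs-chronic significance for meniscus tears contradicts
the printed 30/43 vs 12/17 counts (p ≈ 1).

## Experiment orchestration and problem sizes

`runExperiment` ties the stages together for one (task, plane) pair —
one independent model per pair — with a single experiment seed deriving
per-stage substreams (`deriveSeed`), so a run is reproducible
bit-for-bit from (config, seed, package version).

The package's standing experiment, used by the acceptance script and
test suite, is desk-scale by design: 200 sagittal phantoms at 64 px
(160/40 stratified split), reduced backbone widths (8-32 channels, 16
fused channels), deep dimension 128, 32 hidden units. The architecture
is identical to the full 224/1026 configuration; only widths shrink.
Under these conditions the held-out AUC is expected to clear 0.9, and a
label-shuffled control collapses to chance. Brute-force oracle suites
(naive convolution, sliding-window pooling, pair-counting AUC, exact RBM
enumeration) run on toys of side 16 or smaller and models of 20 or fewer
units.

## Known limitations

* Phantom realism is deliberately minimal (see above); performance
  numbers on phantoms say nothing quantitative about clinical MRI.
* The traditional feature set is a stand-in; swapping it changes
  downstream numbers.
* `weightsMode = "seeded_random"` is a fixed random extractor, not a
  pretrained network; with a checkpoint the pipeline accepts trained
  weights unchanged.
* Exact likelihoods and marginals require enumeration and are limited to
  small models; at full feature dimension only the CD updates and the
  supervised head operate.
* Single train/test split; no cross-validation or hyperparameter search.
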