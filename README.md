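# kneefusion

Multimodal feature fusion for knee MRI injury classification, validated
on synthetic phantoms.

## What this is for

Anterior cruciate ligament (ACL) and meniscus tears dominate knee
injuries. On T2-weighted MRI an intact ligament is a dark band and a
tear is a focal high-signal interruption of it; radiologists grade ACL
damage 0–III (normal / partial damage < 50% / damage ≥ 50% / complete
rupture) against arthroscopy as the surgical reference. `kneefusion` is
for people who want to study — with fully reproducible, desk-scale
experiments — a fusion pipeline of the kind used for this task:

* a **phantom generator** that draws seeded, labeled knee-like slices
  (sagittal / coronal / transverse) with controllable tear lesions,
  since no patient images are publicly available;
* a **frozen convolutional backbone** (five blocks, block *g* mapping to
  spatial side `input / 2^(g-1)`) with **top-down pyramid fusion**: each
  fused map is 2× nearest-neighbour upsampled, summed pixelwise with a
  lateral 2×2 convolution of the raw map below, then smoothed by a 5×5
  convolution,

  `K(g-1) = up2(H'(g)),  H'(g-1) = conv5x5( conv2x2(H(g-1)) + K(g-1) )`;
* a **head** — per-channel batch normalization
  `γ (x - μ) / sqrt(σ² + ε) + δ`, ReLU, adaptive max pooling with
  `stride = floor(In/Out)`, `kernel = In - (Out-1)·stride`, and a frozen
  affine projection to the deep feature vector (default dimension 1026);
* 32 handcrafted **traditional features** (intensity, histogram,
  gradient, co-occurrence texture, dark-region shape);
* an **energy-based fusion classifier**: a restricted Boltzmann machine
  over the scaled concatenation `m = (c, o)` with energy
  `E(x, y) = -t·x - β·y - x'Θy`, marginal
  `p(x) = Z⁻¹ Σ_y e^{-E(x,y)}`, trained by contrastive divergence on
  `Σ_j log p(x_j)` and finished with a logistic output unit; calls are
  positive when the predicted probability is ≥ 0.5;
* **metrics** (confusion counts, accuracy, recall, sensitivity,
  specificity, trapezoidal ROC/AUC equal to pair counting) and
  **clinical concordance statistics** (Pearson chi-square on grade
  tables, grade-0-negative diagnostic stats, concomitant-injury positive
  rates) that operate on published count tables.

Exact RBM marginals, partition functions and log-likelihoods are
available by enumeration for models of ≤ 20 units, which is how training
is audited.

## Worked example

```r
library(kneefusion)

# 200 sagittal phantoms: tear prevalence 0.5, lesion contrast 0.4, noise 0.1
set <- generateDataset(phantomConfig(nImages = 200, seed = deriveSeed(1, "phantom")))
sp  <- splitDataset(set, imageLabels(set)$acl_tear, 0.8, seed = deriveSeed(1, "split"))

rep <- runExperiment(sp$train, sp$test, taskSpec("acl_tear", "sagittal"),
                     backbone = backboneConfig(fusedChannels = 16L),
                     head = headConfig(deepDim = 128L), seed = 1)
rep
#> EvaluationReport [acl_tear / sagittal], seed 1, config 0fb01628
#>   accuracy 0.9000  recall 0.8500  AUC 0.9387
#>   TP=17 FP=1 TN=19 FN=3
```

Of the 40 held-out phantoms, 36 are called correctly at the 0.5 rule
(17 true positives, 19 true negatives); the probability that a random
torn phantom outranks a random intact one (AUC) is 0.94. The same seed
reproduces these numbers bit-for-bit. A label-shuffled control run
(`shuffleLabels = TRUE`) collapses to chance (AUC 0.41 here), confirming
the signal comes from the labels and not from leakage.

The published grade-concordance computation:

```r
gt <- readGradeTable(system.file("extdata", "grade_table.csv", package = "kneefusion"))
chiSquareTest(counts(gt))[c("statistic", "df", "p.value")]
#> $statistic
#> [1] 2.438923
#> $df
#> [1] 3
#> $p.value
#> [1] 0.4864302
```

With p = 0.49 the MRI and arthroscopy grade distributions over the same
60 knees show no detectable difference.

A thin CLI wraps the same functions
(`inst/exec/kneefusion simulate|featurize|train|evaluate|stats`, see
`--help`-style usage in the script header).

## Package layout

S4 classes with validity checks (`PhantomConfig`, `LabeledImage(Set)`,
`FeaturePyramid`, `BNParams`, `RBMModel`, `ConfusionMatrix`,
`GradeTable`, `TaskSpec`, `EvaluationReport`), camelCase accessors, and
Rcpp kernels for the convolution/pooling inner loops. The methods
vignette (`vignettes/multimodal-fusion.Rmd`) documents the model,
defaults, numerical choices and limitations in detail.
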