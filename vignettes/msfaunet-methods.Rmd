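---
title: "Segmenting the thyroid on CT: model, training procedure and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the thyroid on CT: model, training procedure and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The thyroid is an organ at risk in head-and-neck and breast radiotherapy.
On localization CT it is small (a fraction of a percent of a 512 × 512
slice) and is surrounded by blood vessels and other soft tissues of nearly
identical attenuation, so plain intensity rules cannot delineate it and
naive pixel classifiers drown in class imbalance.  `msfaunet` implements a
convolutional encoder–decoder for this task that combines three ideas:

1. **U-Net topology** — an encoder that reduces resolution, a decoder that
   restores it, and skip connections that carry high-resolution detail to
   the decoder.
2. **Parallel multi-resolution branches with repeated fusion** (in the
   HRNet spirit) — instead of a single stream that only descends, the
   encoder maintains branches at full, 1/2, 1/4, … resolution, runs a
   feature-extraction block on each branch per stage, and *fuses* all
   branches after each stage by summing resolution-converted copies, so
   semantic context and precise localization inform each other
   throughout, not only at the bottleneck.
3. **Channel attention (cSE) inside residual blocks** — each block's
   features pass a squeeze-and-excitation gate that pools every channel
   to a scalar (global average pooling), pushes the channel vector
   through a two-layer bottleneck (halved width, ReLU, then restored
   width, sigmoid) and rescales channels by the resulting gate in (0,1).

## The building blocks

**Attention residual block.**  `conv3×3 → BN → ReLU → conv3×3 → BN → cSE`,
summed with a projection shortcut `conv1×1 → BN`.  Downsampling between
levels uses 3×3 *stride-2 convolutions* rather than max pooling (pooling
discards information; a strided convolution learns what to keep), and
upsampling uses 3×3 stride-2 transposed convolutions that exactly double
height and width.

**Multi-scale fusion.**  With active branches $1..k$ (branch $i$ at
resolution $1/2^{i-1}$), the fused output of branch $i$ is
$\mathrm{ReLU}\!\big(\sum_j T_{j\to i}(x_j)\big)$ where $T_{j \to i}$ is the
identity for $j=i$, a chain of $i-j$ stride-2 convolutions for $j<i$, and
a chain of $j-i$ transposed convolutions for $j>i$.  Summation (rather
than concatenation) is the convention of multi-resolution networks and
keeps widths fixed; concatenation is reserved for the decoder's skip
connections.  A dropout layer (rate 0.2) follows each skip concatenation,
guarding against the overfitting risk that repeated fusion brings on
small datasets.

**Loss.**  The smoothed soft Dice loss

$$\mathrm{DL} = 1 - \frac{2\sum_i p_i t_i + \varepsilon}
                        {\sum_i p_i + \sum_i t_i + \varepsilon},$$

averaged over the samples of a batch, with $\varepsilon = 1$ by default
(the usual V-Net-style smoothing; $\varepsilon$ only has to be positive to
avoid 0/0 on empty masks).  For binary predictions the loss tends to
$1 - \mathrm{DSC}$ as $\varepsilon \to 0$; the smooth form over
probabilities is what makes it differentiable for training.  Training on
overlap rather than per-pixel cross-entropy is what makes the tiny
foreground tractable.

**Evaluation indices.**  DSC $=2TP/(2TP+FP+FN)$, JSC $=TP/(TP+FP+FN)$
(so JSC $=$ DSC$/(2-$DSC$)$ always), PPV $=TP/(TP+FP)$,
SE $=TP/(TP+FN)$, and the exact symmetric Hausdorff distance
$H(X,Y)=\max\{h(X,Y),h(Y,X)\}$,
$h(X,Y)=\max_{x\in X}\min_{y\in Y}\lVert x-y\rVert$, between foreground
point sets — the maximum, not a percentile surrogate.  Reports aggregate
per-case values as mean ± sd plus box-plot statistics.  Conventions for
degenerate cases: empty-vs-empty masks score DSC = JSC = 1 and HD = 0;
PPV/SE with empty denominators are reported `NA` and excluded from
aggregation; one empty mask against a nonempty one gives HD = `Inf`.

## Preprocessing and augmentation

Stored CT pixels are converted to Hounsfield units by the DICOM rescale
(`hu = raw × slope + intercept`), windowed to `[0, 1]` with a soft-tissue
neck window (level 60 HU, width 400 HU — thyroid tissue at roughly 60–100
HU sits inside it; the window is configurable because no universal value
exists), then contrast-enhanced with CLAHE (8 × 8 tiles, clip factor 2;
the contrast-*limited* variant is used because unlimited adaptive
equalization amplifies noise).  A constant image passes through the
equalizer unchanged — there is no contrast to enhance.

Training augmentation draws one random transform per image per epoch:
rotation ±15°, horizontal flip with probability 0.5, isotropic zoom
0.9–1.1, shear ±8°.  The identical geometric map is applied to image
(bilinear) and mask (nearest neighbour, re-binarized at 0.5), and
augmenting on the fly is equivalent to pre-expanding the dataset on disk
without the storage.  Ranges are package choices; the augmentation family
itself (rotate / flip / zoom / shear) is fixed.

## Training procedure

Adam (β₁ = 0.9, β₂ = 0.999) minimizes the Dice loss with a *staircase*
exponential schedule: `lr(step) = initial_lr × decay_rate^floor(step /
decay_steps)`, a step being one optimizer iteration.  The reference
operating point for clinical-scale inputs is batch 2, 120 epochs,
512 × 512 inputs, initial rate 2·10⁻⁴, decay 0.96 every 300 steps, with
4 branches of widths 32/64/128/256.  The optimizer identity and the
staircase (vs. continuous) reading of the decay are package choices —
plain SGD is exposed as an option; Adam is the default because fixed
exponential schedules with rates in the 10⁻⁵–10⁻⁴ range are typical Adam
settings.  Each epoch ends with a validation pass (Dice loss and DSC at
threshold 0.5); the weights kept are those of the best-validation epoch,
and training runs the fixed number of epochs with no early stopping.
Weight init is He-uniform for convolutions, zeros for biases; everything
downstream of the seed (shuffling, augmentation, dropout) is derived from
the configured seed, so a run is exactly reproducible.

The engine itself — convolution, transposed convolution, batch
normalization, the attention and fusion blocks, and reverse-mode
backpropagation through all of it — is implemented in the package
(Armadillo-backed im2col/col2im kernels plus a small define-by-run tape in
R), and its gradients are verified against central finite differences in
the test suite.

## The phantom study

No clinical images ship with the package, so every end-to-end claim is
exercised on synthetic CT-like phantoms: a bilobed gland (two jittered
ellipses joined by an isthmus band) drawn at thyroid-like HU (60–100)
over uniform neck soft tissue (40 HU), surrounded by vessel-like circular
confounders drawn from an *overlapping* HU range — so gland-vs-vessel is
an intensity ambiguity exactly as on real CT — plus additive Gaussian
noise (sd 8 HU).  Vessels are rejection-sampled off the gland so labels
stay exact.  Generation is a pure function of (config, index): the
per-phantom stream is seeded with `seed + index`, which makes datasets
byte-reproducible including their DICOM encodings.

The desk-scale study conditions, fixed once: 80 phantoms at 64 × 64
pixels, split 6:1:1 by case into 60/10/10, a small network (3 levels,
base width 8, ≈85k parameters), batch 2, 12 epochs, initial learning
rate 2·10⁻³ with the 0.96/300 staircase.  Two deliberate departures from
the clinical operating point, both consequences of the 64-fold smaller
images and ~100-fold smaller model: the learning rate is scaled up
(2·10⁻⁴ is matched to the full-size problem and underfits the small one
within a short budget), and 12 epochs suffice where the full-size problem
uses 120.  The capacity check (4 noise-free phantoms driven to a training
Dice loss below 0.05) uses rate 10⁻² for the same reason.  These sizes are
the package's own choices of experimental scale.

What passing the phantom study shows — and what it does not.  It shows the
whole pipeline is wired correctly: preprocessing, augmentation,
optimization, checkpoint selection, inference and scoring, with a test
DSC well above 0.8 and finite Hausdorff distances.  It does *not*
certify clinical performance: phantoms mimic the intensity ambiguity and
topology of the thyroid but not anatomical shape variation, scanner
noise spectra, or annotation variability.  Published clinical numbers for
this architecture class (DSC ≈ 0.90 ± 0.09 on 80-patient data) come from
data that is not publicly deposited and are out of reach of a synthetic
study by construction.

## Numerical and interface choices

* Binarization threshold for probability maps: 0.5 (configurable).
* BN: ε = 10⁻⁵, running-statistics momentum 0.1; inference uses running
  statistics, so batch members never interact at prediction time.
* Hausdorff distance is computed between foreground pixel centers scaled
  by the pixel spacing, in pixels when no spacing is given (reported HD
  values are unit-ambiguous in parts of the literature; making spacing
  explicit avoids that).
* Masks on disk are 8-bit PNG 0/255; in memory strictly {0,1};
  any nonzero pixel reads as foreground.
* Images on disk are single-frame explicit-VR little-endian DICOM with
  stored pixels = HU + 1024 (slope 1, intercept −1024).  The reader
  handles exactly this profile and fails loudly on anything else;
  missing rescale tags default to slope 1 / intercept 0 with a warning.
* Dataset splitting uses largest-remainder rounding and guarantees every
  partition at least one case; splitting is by case (patient), never by
  slice, to prevent leakage.
* Input sizes must be divisible by 2^(levels−1); the forward pass checks
  and names the violated constraint rather than mis-padding silently.
* Decoder skips carry *post-fusion* encoder features (the fused maps are
  the best-informed version of each branch; the alternative pre-fusion
  wiring is not exposed).
* Where a published architecture figure leaves branch widths and fusion
  multiplicity unspecified, this implementation uses U-Net-like doubling
  widths and one fusion round per encoder stage — the minimal reading of
  "fusion after each attention residual block".

## Known limitations

Strictly 2-D (per-slice) segmentation and metrics; single foreground
class; the CPU engine is written for correctness and desk-scale
experiments, not for 512 × 512 × 120-epoch clinical training runs, which
would want a GPU framework; the DICOM layer is a deliberate minimal
profile, not a general implementation.
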