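---
title: "Hierarchical multi-task networks for conjunctival disease screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multi-task networks for conjunctival disease screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Diabetes alters microvessels throughout the body. The bulbar conjunctiva —
the vascularized mucosa over the white of the eye — exposes microvessels to
direct photography without specialised fundus equipment, and diabetic
changes there include thickening of the vascular wall, abnormal
perivascular color, morphological distortion (tortuosity) and
microaneurysms. These changes are subtle: individually they are hard to
read even for trained observers, and a single end-to-end classifier trained
on scarce labelled images tends to latch onto incidental features.

The hierarchical multi-task network (HMT-Net) implemented here attacks the
problem the way an ophthalmologist would: it first learns four *simpler*
binary sub-questions about an image —

* **Q1** — are vessels abnormally widened?
* **Q2** — is the perivascular color abnormal?
* **Q3** — are vessels tortuous / morphologically distorted?
* **Q4** — are microaneurysms present?

— and only then learns the hard question, **Q5**: does the subject have the
disease? Each sub-question is answered by an **F-Net**, a residual
convolutional feature extractor with a global-average-pooling (GAP) +
fully-connected (FC) binary softmax head.

## Architecture

**Stage-I.** One F-Net per sub-question is trained on Dataset-I with
two-category cross-entropy. The full-scale backbone is a ResNet50-style
four-stage bottleneck network (terminal feature channels 2048, total
spatial downsampling ×32); the package also provides a *tiny* variant
(terminal channels 64, downsampling ×8, a stride-2 stem followed by two
basic residual stages) whose operation surface is identical and which makes
every experiment in this vignette runnable on one desk CPU.

**Stage-II.** The four trained F-Nets lose their GAP/FC heads; their
feature-extraction layers are kept and **frozen** — every parameter,
including batch-normalisation statistics, is conserved bitwise from here
on. A fifth, trainable branch, F-Net(sup), is added with the same
architecture. For an input image the five branches produce feature maps
F1..F4 and F5⁰, which are concatenated along channels: at full scale
5 × 2048 = **10,240** channels.

The fusion network then applies:

1. **Channel attention** — a squeeze-and-excitation-style gate: global
   average per channel → bottleneck linear layer (reduction ratio 16,
   rectified) → expansion linear layer → sigmoid, giving one weight in
   (0,1) per channel, which multiplies that channel. The choice of the
   squeeze/excite form is ours: per-channel attention weights computed
   adaptively from the features admit several parameterisations, and this
   is the standard one for exactly this "assign suitable weights to
   channels" role.
2. **Two compression convolutions** — kernel size 3, stride 1, padding 1
   (so the spatial size is preserved, as the channel arithmetic implies),
   with 4096 and 2048 output channels at full scale: the concatenated
   features are compressed 10,240 → 4096 → 2048. A rectifier sits between
   and after the two convolutions (the nonlinearity choice is ours; the
   compression widths are not). At tiny scale the widths scale
   proportionally to the concatenated width — 320 → 128 → 64 — rounded to a
   multiple of 8 with floor 8.
3. **Classifier head** — GAP, an FC layer to two logits and a softmax over
   {healthy, diseased}; disease is the positive class throughout.

Stage-II training updates only the sup branch, the attention/compression
fusion and the head; a frozen-branch checksum is conserved by construction
and asserted in the tests. Branch concatenation order is fixed (Q1..Q4,
sup) for reproducibility. Attention is applied once, on the concatenated
block; applying it per branch before concatenation is a plausible
alternative reading that we did not adopt, because the gate is then unable
to weigh branches against each other.

Reduced variants with any subset S of the four sub-question branches are
available; S = ∅ is the **baseline**: a single trainable F-Net feeding the
same (width-scaled) fusion and head, i.e. direct end-to-end disease
prediction with matched capacity conventions.

## Why no pretrained backbone

Classical transfer learning would initialise each backbone from a large
general image corpus. This package is self-contained: it offers (a) loading
an externally supplied checkpoint, and (b) a built-in pretext task
(vessel-bearing vs vessel-free synthetic patches, `pretext_pretrain()`);
default initialisation is He-scaled random, which is entirely adequate at
the tiny scale the synthetic experiments run at.

## The synthetic conjunctiva generator

The real corpus this methodology targets is private clinical imagery, so
the package ships a generator whose output exercises every pipeline stage
with known ground truth. An image is a pale-sclera background
(mean RGB (205, 175, 165)) crossed by 2–4 dark-red vessels drawn as
smoothed random curves (a random walk smoothed by a fixed moving-average
kernel of width a quarter of the image side, scaled to a target
perpendicular amplitude) and stroked at a base width of 2.5 px. The four
abnormalities are rendered, each with a per-abnormality ground-truth mask:

| flag | rendering | default parameters |
|------|-----------|--------------------|
| Q1 | stroke width multiplied | ×1.9 |
| Q2 | dilated perivascular band tinted | ΔRGB (+35, −25, −25) |
| Q3 | abnormal tortuosity amplitude | 6 px vs 1.5 px normal |
| Q4 | dark dots adjacent to vessels | 3–6 dots, radius ≈ 1.2 px |

Gaussian pixel noise (sd 6 on the 8-bit scale) is added, and — for
quality-filter fixtures — a flat occluder can cover a recorded fraction of
one image edge.

**Label model.** Disease status (Q5) is a *subject-level* property.
Conditional on it, each abnormality appears on each image independently
with probability 0.75 (diseased) or 0.15 (healthy). The link between
Q1–Q4 and Q5 is therefore statistical, never deterministic — with four
conditionally independent cues at these rates the Bayes accuracy of
predicting Q5 from perfectly read cues is ≈ 0.92, so the Q5 task is
genuinely harder than Q1–Q4 and leaves room for the sub-task features to
help, which is the phenomenon the architecture exists to exploit. The
rates are our choice (made once): high enough penetrance that a diseased
subject usually shows some abnormality, low but nonzero background rate in
healthy subjects, as one would describe a moderately specific clinical
sign.

**Corpus shape.** The default spec emulates a 611-image screening corpus:
405 images from 68 diseased subjects and 206 from 62 healthy subjects,
allocated near-evenly per subject, at 64 × 64 px. Identical spec + seed
reproduce the corpus byte-for-byte.

**What the generator does not emulate:** photorealistic sclera texture,
illumination/camera variation, A/V ratio or blood-flow phenomena, eyelid
anatomy, and correlated abnormalities (flags are conditionally
independent). Passing tests on this corpus therefore demonstrate that the
*machinery* — two-stage training, freezing, fusion, evaluation — behaves as
specified, and that the architectural benefit direction is reproducible on
data with the stated statistical structure; they say nothing about
clinical performance on real photographs.

## Data pipeline choices

* **Quality filter.** An image is excluded iff occlusion > 1/10 of the
  image, or contrast (grayscale sd) below a threshold, or sharpness
  (variance of a Laplacian response) below a threshold. Numeric
  contrast/blur thresholds default to the 5th percentile of a reference
  healthy pool (`default_quality_thresholds()`), since no absolute values
  are canonical; the 1/10 occlusion rule is absolute.
* **Valid-region segmentation.** The statistic is the 5×5 local standard
  deviation of the grayscale image, thresholded by Otsu; because Otsu
  always splits the histogram somewhere, the threshold is bounded above by
  half the median statistic so homogeneously textured (fully valid) images
  are not split along vessel edges; the largest connected component is
  kept, morphologically closed and hole-filled. Flat occluders fall below
  threshold; constant images yield an empty mask with a warning flag.
* **Augmentation.** The identity image, one copy per configured rotation
  (90/180/270° by default; arbitrary angles supported with
  nearest-neighbour resampling and background fill) and flips, plus one
  *masked-noise* copy: noise is added only outside the valid region, and
  pixels inside it are bitwise unchanged — the augmentation never corrupts
  the region that carries the signal.
* **Splitting.** Fivefold cross-validation is the protocol default. The
  split unit defaults to *subject* so no subject's images straddle a fold
  boundary (image-level splitting is available, matching published per-fold
  image tallies, which are image counts). Folds and the Dataset-I/II
  partition are stratified by Q5 and deterministic under their seeds. The
  Stage-I/Stage-II portions are drawn 50/50 from each fold's training side;
  how those portions interact with the outer folds is not canonically
  fixed, so both mechanisms are exposed and composed in
  `run_crossvalidation()` under a strict no-leakage rule: no test image of
  a fold enters *any* training stage of that fold (audited from logged path
  sets; violation is a hard failure). The baseline model, which has no
  Stage-I, trains on the Dataset-II portion only, so it sees exactly the
  images the fused model's trainable parts see.

## Training and numerical choices

* Loss: two-category softmax cross-entropy; optional inverse-frequency
  class weights (off by default).
* Optimizer: adaptive moments (Adam), learning rate 1e-3 by default;
  gradient descent with momentum is available. `train_config()` defaults to
  30 epochs, batch 32.
* The cross-validation driver defaults to 4 epochs per stage at learning
  rate 2e-3 — the desk-scale budget we chose for the fivefold × 3-seed
  synthetic experiments (a full run trains 4 × 5 Stage-I networks, 5 fused
  models and 5 baselines per seed); the separable-task tests confirm the
  tiny backbone fits its training data well within this budget.
* Initialisation: He-scaled normal, deterministic per seed; batch-norm
  momentum 0.1, eps 1e-5. All randomness flows through R's RNG, so every
  training run is bit-reproducible given (data, seeds, single-threaded
  BLAS).
* Frozen semantics are strict: freezing conserves weights *and*
  batch-norm running statistics; frozen branches always run in inference
  mode, and their features are computed once per Stage-II run and cached.
* Evaluation: SE = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/total, with
  disease positive. Hard calls threshold the softmax probability at 0.5
  (no canonical operating point exists; 0.5 is the symmetric choice).
  Undefined metrics (zero denominator) are reported as missing, never as
  0, so fold averages are not silently inflated. ROC curves sweep every
  distinct score (ties grouped at one threshold); AUC is the trapezoidal
  integral, which equals the midrank pair statistic
  P(s⁺ > s⁻) + ½P(equal) — asserted against an O(n²) oracle in the tests.
  ROC/AUC are image-level (subject-level pooling is a possible alternative
  that the package does not currently implement).
* CAM: classic GAP-weight class activation mapping — both model heads end
  in GAP+FC, the exact setting where it applies; gradient-based variants
  are out of scope. For the HMT-Net the map is computed on the fused
  post-compression features, the only GAP+FC head in the model. Maps are
  clipped at zero, normalised to [0,1] (re-normalised after bilinear
  upsampling so the extremes are exact), and constant maps are flagged and
  reported as uniform 0.5. The `localization_score()` — in-mask fraction of
  heatmap mass — has the mask's area fraction as its uniform-attention
  baseline, which is the comparison the tests make.

## Problem sizes used by the shipped experiments

The test-suite experiments run the tiny backbone at 64 × 64: the benefit
comparison uses the full default corpus (611 images, 5 folds, 3 seeds);
CAM localization trains one Q2 network on 160 images for 8 epochs;
freeze-conservation runs 2 + 3 epochs on a 48-image corpus. The full-scale
architecture checks instantiate the real 2048-channel, five-branch model
and forward one 64-px image (channel counts are input-size invariant).

## Known limitations

* The tiny backbone's stride-2 stem halves resolution immediately;
  1–2-pixel microaneurysms are at the edge of its receptive acuity, and Q4
  test accuracy is accordingly the weakest of the four sub-tasks.
* Attention variants (spatial, per-branch, transformer-style) and more
  than two compression stages are deliberately out of scope.
* The CNN engine is purpose-built (im2col + GEMM via RcppArmadillo, exact
  hand-derived backpropagation, verified by finite differences in the
  tests); it is single-threaded and CPU-only by design and does not aim to
  compete with general deep-learning frameworks.
* Whether sub-questions should be multi-category rather than binary cannot
  be settled from the available description; binary is assumed throughout,
  consistent with "normal / abnormal" reading of each sign.
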