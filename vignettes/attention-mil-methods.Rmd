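---
title: "Attention-based multiple-instance learning for referable DR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multiple-instance learning for referable DR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retinamil)
```

This vignette explains the models and procedures implemented in
`retinamil`, the choices that were genuinely open, and what the bundled
synthetic data can and cannot demonstrate.

## The problem and the model

Referable diabetic retinopathy (moderate-or-worse DR) is decided from a
fundus photograph by the presence and load of small lesions:
microaneurysms (dark dots of a few pixels), haemorrhages (larger dark
blobs) and exudates (bright yellow deposits). The diagnostic evidence is
spatially sparse; a whole-image classifier must implicitly find it, and
gives no account of where it looked.

`retinamil` makes the sparsity explicit. An image is reduced to a *bag*
of `K` patches `X = {x_1, …, x_K}`. Any permutation-invariant set
function can be written as a sum decomposition `ρ(Σ_k φ(x_k))`; inserting
a learned convex weighting gives the attention-MIL form

$$p(y\,|\,X) = \rho\Big(\sum_{k=1}^{K} \alpha_k\, \phi(x_k)\Big), \qquad
\alpha_k = \frac{\exp(w^\top \tanh(V h_k))}{\sum_j \exp(w^\top \tanh(V h_j))},$$

with `h_k = φ(x_k) ∈ R^M`, `V ∈ R^{L×M}`, `w ∈ R^L`. The weights `α`
sum to one by construction, so the bag embedding `z = Σ α_k h_k` is a
convex combination of patch features and the prediction is exactly
invariant to patch order (the test suite asserts this to 1e-6 on random
bags). Supervision is the image label only, through the standard
two-term binary cross-entropy with probabilities clamped at `1e-7`.
Because only attention can raise a patch's influence, a trained model's
`α` is itself a weak lesion detector — the package's evaluation module
quantifies exactly that.

## Preprocessing

Fundus images arrive at arbitrary resolutions with the circular retina
disk framed inconsistently and often vertically clipped. The pipeline is:

1. **Disk localisation.** Gradient-direction circle Hough voting on an
   edge map of the (slightly blurred) green channel, radii swept over
   `[0.2, 0.6]·min(H, W)` on a copy downsampled to a 512-px long side,
   followed by a least-squares circle fit on the edge inliers. The vote
   peak is normalised by the circle's in-frame circumference so clipped
   disks score fairly; images whose best score falls below
   `score_threshold` (default 0.2) raise a classed condition and are
   discarded by callers. On the synthetic generator the fit recovers the
   planted radius to well under 1%.
2. **Clip padding.** If `center ± radius` leaves the frame vertically,
   zero rows are prepended/appended by exactly the deficit.
3. **Crop and resize.** The square of edge `crop_edge_factor · r`
   centred on the disk is cropped and bilinearly resized to 512×512.
   The crop factor is configurable with default 2 (the `2r` bounding
   square), so the whole disk inscribes the frame; an edge of `r`
   literally would cut half the disk away, which no screening pipeline
   wants and which contradicts how preprocessed fundus images look.
4. **Local colour-average subtraction.**
   `clip(a·(I − G_σ(I)) + bias)` with `a = 4`, `bias` mid-gray and
   `σ = out_size/30` — the widely used Kaggle-winning normalisation
   recipe. It flattens illumination and roughly multiplies local
   lesion contrast by `a`.
5. **Boundary mask.** The outer 5% of the disk radius is zeroed
   (filter edge artefacts); the indicator of the shrunken disk is the
   binary retina mask used everywhere downstream. The invariant
   `image[mask == 0] == 0` is maintained by every stage, including
   augmentation.

Coordinates are 1-based `(row, col)` with windows spanning
`row … row+d−1`, the natural convention in R; all printed window counts
are unaffected by this choice.

## Bags of patches

Training uses the *random-K* policy: `K = 50` origins drawn uniformly,
without replacement while possible, from **all pixel-resolution**
window positions whose retina content is at least 50% (the "pool of
possible patches" is read literally, not grid-restricted). Each epoch
therefore sees a different representation of the same image — cheap,
implicit augmentation. Test time uses the exhaustive grid with overlap
ratio `t`; the stride is `round(d(1−t))` with no extra boundary window,
which reproduces the canonical counts 225 (`t=0.5`), 841 (`t=0.75`) and
3249 (`t=0.875`) for a 512 frame with `d = 64`. Classification defaults
to `t = 0.75`; heatmaps default to `t = 0.875` because coverage
granularity, and hence visual quality, increases with overlap. These
are two separate configuration keys.

## The compact encoder and training

No deep-learning framework is available to this package, so the encoder
`φ` is implemented directly in RcppArmadillo: four blocks of 3×3
stride-2 convolution (channels 3→8→16→32→64, im2col GEMM), each
followed by **per-patch instance normalisation** with a learned
per-channel scale and shift, then ReLU; global average pooling; and a
linear map to `M = 128` features. Inputs are centred to `[-1, 1]`.
Instance normalisation — statistics over the spatial positions of each
patch's channel map — was chosen over batch statistics deliberately:
it keeps each feature row a function of its own patch alone (the
per-instance encoder contract, preserved even during training), it
needs no train/eval mode split or running averages, and it conditions
the optimisation well enough that the model trains from scratch at
batch size one. Without it, the loss barely moves in the step budget
of the desk-scale experiment; with it, held-out AUC exceeds 0.9 within
a handful of epochs. The full backward pass (through the softmax
attention, the normalisation, and the im2col convolutions) is
hand-derived and verified against central finite differences in the
test suite.

Training performs one Adam step (base rate 3·10⁻⁴, β = 0.9/0.999) per
image per epoch: augment, draw a random-K bag, backpropagate the BCE.
Augmentation combines one affine warp (shift ±10%, scale 0.9–1.1,
rotation ±180°, random horizontal flip; bilinear for the image, nearest
for the mask, which is warped in lockstep) with photometric jitter
(brightness/contrast ±20%, saturation ±20%, hue ±5% as a rotation about
the RGB gray axis) applied to the image only. These ranges are package
defaults chosen as the standard mild-jitter recipe for fundus imagery;
all are configurable. After every epoch the model is scored on a
validation set and a checkpoint is selected on validation ROC AUC.
Because the AUC estimate on a desk-scale validation set (about a
hundred images) has a standard error of roughly 0.02, selecting the
literal argmax would often latch onto an early, lucky epoch whose
attention is still immature; the rule used is therefore the familiar
one-standard-error variant: keep the *latest* epoch whose validation
AUC is within `val_tol` (default 0.02) of the best seen. Validation
bags use a coarser grid (`val_overlap = 0.5`) than final evaluation
purely to keep model selection cheap; the final metrics are always
computed at the test-time overlap.

The `encoder_kind` configuration currently offers `compact_cnn` only.
A deep residual encoder belongs at full scale with GPU training, both
of which are outside this package's scope; the encoder contract
(patch → M-vector, per-instance) is the documented extension point.

## Heatmaps

Per-patch weights are added onto a zeroed image accumulator over each
patch's pixel footprint, then min–max mapped to `[0, 1]`. Two
numerical conventions: the map is normalised over the full accumulator
(not retina-only), and a constant accumulator — no contrast — maps to
all zeros rather than dividing by zero. With a full in-bounds grid and
`Σα = 1` the accumulator mass is exactly `d²`, a conservation identity
the tests assert. The coverage count (windows per pixel) is retained
alongside for the pixel-level evaluation.

## Evaluating the attention as a lesion detector

Given pixel-level annotations for the three lesion classes (exudates
merge soft and hard), the package scores the attention weights three
ways, on grid bags at `t = 0.875`:

* **Patch level:** a patch is positive for a class if it contains at
  least one annotated pixel; `α` is the score; ROC AUC and AUPRC are
  reported. Patches from several images are pooled by default (counts
  pooled, as in per-dataset reporting); a per-image mode is a flag.
* **Pixel level:** every pixel inherits the mean `α` of the windows
  covering it (a max rule is available as a config alternative);
  pixels covered by no window have no prediction and are excluded.
* **Area regression:** ordinary least squares of `α` on the fraction
  of the patch area annotated as lesion, with Pearson r; a positive
  slope means attention grows with lesion load. Constant fractions
  raise a degenerate-fit condition.

AUPRC is computed as average precision with step interpolation
(thresholds at distinct scores); this matters at small n and is the
convention matched by the test oracles.

## The synthetic generator

The generator emulates what the preprocessing and the learner actually
consume: a bright orange-red disk (radius 0.35–0.45 of the frame) on a
dark background, radial illumination falloff plus two low-frequency
illumination fields and fine noise, dark curvilinear vessel strokes,
and — with probability 0.15 — a vertical clip of 10–30% of the disk
height. Lesions are planted inside the disk with exact masks:
microaneurysms (dark dots, radius 1.5–3 px), haemorrhages (irregular
unions of 3–6 dark lobes, base radius 4–12 px), exudates (bright
yellow blobs, radius 3–10 px). Positive images draw per-class Poisson
counts (means 8 / 2.5 / 2.5), redrawn until the label rule holds;
the label is 1 iff at least one haemorrhage or exudate is present or
at least five microaneurysms — a moderate-or-worse surrogate.
Negatives carry no lesions except, in 15% of cases, one to four
sub-threshold microaneurysm distractors, so "any dark dot" is not a
shortcut. Lesion contrast is configurable because it sets task
difficulty; the defaults were chosen so that the Graham normalisation
amplifies rather than erases the lesions (a generator self-test in the
suite checks post-normalisation lesion contrast ≥ 0.15). Two images
share each synthetic subject id to exercise per-subject aggregation.

What the generator does **not** model: optic disc and fovea anatomy,
camera-specific colour responses, focus/motion blur, compression
artefacts, gradability problems, or lesion photometry textured like
real pathology. Passing the desk-scale experiment therefore shows the
pipeline, optimisation and attention mechanism work end-to-end on
images with the right coarse statistics — it is not evidence of
clinical performance, and the package makes no such claim.

## The desk-scale experiment

`desk_experiment()` is the package's reference experiment and what
`scripts/acceptance.R` runs: 500 synthetic 512-px images at prevalence
0.5 under a fixed seed; preprocessing with discard-on-failure; a
subject-disjoint held-out split of 100 images; training the compact
encoder with `K = 50`, `d = 64`, lr 3·10⁻⁴ for 8 epochs with
validation checkpointing; classification metrics on the held-out split
at `t = 0.75`; and the localisation protocol on 20 held-out positives
at `t = 0.875`. Fourteen epochs (≈ 5600 optimisation steps) is the
budget at which both the validation AUC (which plateaus above 0.9 after
three or four epochs) and the attention's lesion alignment (which keeps
improving for several epochs after that, as the loss falls) have
matured, while keeping the whole experiment under twenty minutes on one
CPU. Problem sizes in the unit tests are
smaller (tens to a couple of hundred images, 256-px frames) and are
chosen to exercise code paths, not performance.

## Known limitations

* Batch size is fixed at one bag; there is no minibatching across
  images (gradient noise is correspondingly high, which the
  validation-checkpoint selection absorbs).
* The Hough detector assumes one dominant circular boundary; montage
  or heavily vignetted images would need the camera-ROI path that is
  deliberately not implemented.
* Probabilities are not calibrated; operating points should be chosen
  on a validation set, as the operating-point functions do.
* Pixel-level attention metrics inherit the patch footprint: they
  quantify localisation at patch resolution, not segmentation quality.
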