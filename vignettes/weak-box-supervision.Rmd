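---
title: "Training segmentation models from bounding boxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training segmentation models from bounding boxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pixel-accurate segmentation masks are expensive to annotate; axis-aligned
bounding boxes are cheap. In colonoscopy imaging, for example, a clinician
can draw a box around a polyp in seconds, while tracing its contour takes
minutes. **boxseg** trains pixel-level segmentation networks when most (or
all) of the training annotation consists of boxes, using three ideas that
work together:

1. **Iterative pseudo-mask refinement.** Each box-annotated image gets an
   initial guess of its mask (a *pseudo-mask*). The network trains on the
   current pseudo-masks for a few epochs, then every pseudo-mask is
   replaced by the network's own prediction — thresholded at 0.5 and
   *clipped* to the boxes (every predicted positive outside all boxes is
   zeroed, since boxes guarantee that nothing outside them is foreground).
   A refresh must also pass the same 30% box-coverage sanity rule that
   the hybrid initializer applies to pre-trained predictions (see below);
   otherwise the image keeps its current target. Alternating training
   and refreshing lets the targets converge towards the true contours.
2. **A ring-shaped confidence weight on the loss.** Near a box's edges the
   pseudo-mask is least trustworthy. The per-pixel loss weight is 1 at the
   box centre (certainly foreground) and far outside the box (certainly
   background), and drops to 0 along an oval ring spanning the box, with a
   smooth `|d - midline|^1.5` ramp between the regimes. The network is
   thus scrutinized only where the labels are reliable and left free to
   use image evidence in the uncertain band.
3. **Mixed supervision.** Images that do have human masks train with unit
   loss weights and are never refined; they can be pooled freely with
   box-only images in the same batches.

## The loss

With prediction $P$, target $Y$ and weight mask $M$ (all
batch × height × width),

$$\mathrm{MaskedLoss}(P, Y, M) \;=\; \frac{1}{\sum M}\,
  \sum M \odot \mathrm{BCE}(Y, P),
  \qquad \mathrm{BCE}(y,p) = -\bigl[y\log p + (1-y)\log(1-p)\bigr],$$

with probabilities clamped to $[10^{-7}, 1-10^{-7}]$ (the formula is
undefined at 0 and 1). The $1/\sum M$ normalization makes the loss
invariant to rescaling $M$ and comparable across batches with different
amounts of down-weighted area. With $M \equiv 1$ it reduces to the plain
mean binary cross-entropy. The gradient is taken through the sigmoid as
$M (p - y) / \sum M$, the exact gradient of the unclamped loss and the
standard numerically stable implementation; the clamp affects only the
reported loss value.

### Ring geometry and the distance metric

`build_loss_mask()` follows the published construction literally: with a
box of size $w \times h$, it sets `inner_radius` $= \min(w,h) \cdot
d_\mathrm{in}/2$ and `outer_radius` $= \max(w,h) \cdot d_\mathrm{out}/2$
(defaults $d_\mathrm{in} = 0.6$, $d_\mathrm{out} = 1.0$, both
configurable — the reference construction leaves their values open, and
$d_\mathrm{out} = 1$ makes the ring reach the box edges), and compares
them against the field

$$d(x, y) = \frac{(x - c_x)^2}{s_x} + \frac{(y - c_y)^2}{s_y},$$

where $s_x, s_y$ are the box aspect ratios. Note that $d$ is a sum of
*squared* pixel offsets while the radii are *linear* in the box size: in
this literal form the zero-weight ring sits at pixel radius
$\approx\sqrt{0.4\,s}$ for a square box of side $s$ — a few pixels wide
at any realistic box size, so almost the whole box interior receives full
confidence. Trained that way, the network has no freedom in the boundary
band: on our benchmarks it memorizes the circular pseudo-targets and the
refinement loop reproduces them (measured final dice 0.69, *below* the
0.72 of the initial circles).

`loss_mask_params(distance = "euclidean")` therefore offers the variant
that takes the square root of $d$ first, which places the ring between
$0.3\,\min(w,h)$ and $0.5\,\max(w,h)$ in ordinary pixel units — the
geometry the construction describes, with the zero midline at $0.8\times$
half the box side, exactly the band where a circular initial guess and
the true contour disagree. All training benchmarks in this package use
the Euclidean variant; the literal form remains the default of
`build_loss_mask()` and is what the oracle tests verify. Multi-box images
combine per-box masks by element-wise minimum: a pixel is down-weighted
if it is uncertain for *any* box.

## Pseudo-mask initializers

* **Circle (CI):** a solid disc at the box centre with diameter 4/5 of
  the box's shorter side (`circle_diameter_fraction`, up to 1.0). A pixel
  is positive iff its centre lies strictly inside the disc.
* **Prediction (PI):** a pre-trained model's probability map, thresholded
  strictly above 0.5 and clipped to the boxes.
* **Hybrid (HI):** per box, the clipped prediction is kept unless it
  covers less than 30% (`hybrid_area_fraction`, strict) of the continuous
  box area $w \times h$, in which case that box falls back to the circle.
  The 30% rule is applied per box, and multi-box images union the per-box
  decisions.

Every initializer output satisfies positives ⊆ box union by construction.

## The network

No deep-learning framework is assumed: the package ships a compact CPU
U-Net implemented with im2col convolutions on Armadillo. Encoder blocks
are two 3×3 conv + ReLU layers followed by 2×2 max-pooling (ties broken
in favour of the first element in column order); the decoder mirrors them
with 2×2 transpose-convolution upsampling and skip concatenation; a 1×1
convolution plus sigmoid yields a probability map the same size as the
input. Weights use He-normal initialization (`sd = sqrt(2/fan_in)`), zero
biases, so the head starts near probability 0.5. Two presets:

* `unet_full()` — five blocks with VGG16-style widths 64/128/256/512/512
  at 384 px, for completeness with the reference architecture;
  `load_encoder_weights()` accepts externally converted VGG16 encoder
  weights for it (never downloaded at test time).
* `unet_tiny()` — three blocks, 8/16/32 channels, 96 px, ~121k
  parameters. All tests and benchmarks run at this scale: the subject of
  validation is the *training mechanism*, not model capacity.

Training uses Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8). The reference
schedule (`training_schedule()`) is batch 12, epochs [3,3,6,6,6,6,6,6],
learning rate 1e-4 with inverse-time decay `lr/(1 + 5e-4·e)` from the
third iteration (a multiplicative reading of a "decay factor" of 5e-4
would collapse the rate after one epoch, so the inverse-time reading is
the only one consistent with continued learning), and early stopping
when the validation loss fails to improve by more than 1e-5 for two
consecutive iterations. Validation loss is computed with the same ring
masks as training, so no ground truth is consumed before final
evaluation; validation pseudo-targets are refreshed alongside the
training targets. The desk-scale schedule (`desk_schedule()`) uses
learning rate 3e-3 — 1e-4 belongs to large pretrained encoders; a small
network trained from scratch needs a conventionally larger step — with
batch 12 and no early stopping. Optimizer state is kept across refinement
iterations (refreshing the targets does not reset Adam's moments). All
randomness (weight init, shuffling, augmentation) derives from the
schedule's single seed.

## Preprocessing and augmentation

Images are resized by `target_size / max(H, W)` preserving aspect ratio
and padded symmetrically with zeros to a square (480×640 frames become
288×384 content between two 48-px bands); boxes and masks are mapped by
the same transform, masks with nearest-neighbour interpolation to
preserve binarity, and the mapping is invertible on boxes to within a
pixel. Intensities are normalized by per-channel training-set statistics
computed once per run and attached to the trained model, so inference
and initializer predictions always see the training-time preprocessing;
a per-image mode exists. Four augmentations are available: integer
translations up to 60 px clamped so no box leaves the image, zoom ±10%
about the image centre, independent horizontal/vertical mirroring, and
additive per-channel colour shifts drawn from Normal(0, 0.1) applied to
normalized intensities (after normalization, since the shift is defined
on that scale). The benchmarks below train without augmentation: at 96 px
with 200 scenes the augmentation machinery costs more time than it buys
accuracy, and the properties under test do not involve it.

## The synthetic benchmark suite

`generate_dataset()` produces seeded scenes that emulate the *structure*
of box-annotated colonoscopy data: a smooth reddish textured background,
one bright textured blob per scene (a deformed ellipse — random-phase
radial perturbation up to 12% of the radius — so that a circular initial
guess is informative but never exactly right), an exact rasterized
ground-truth mask, a tight bounding box, optionally a loose box (each
side dilated by a padding fraction) and optionally a bright
instrument-like bar crossing the scene. Per-scene randomness is derived
by counter-based seed splitting, so scene *i* is bit-identical regardless
of how many scenes are generated. Pixels are quantized to 8 bits so the
PNG round trip is exact.

What the generator does *not* emulate: specular highlights, motion blur,
fluid/debris, vignetting, inter-patient appearance shifts, and polyps
whose brightness matches the background. Passing benchmarks therefore
demonstrates that the refinement mechanism recovers contours when the
object class is learnable from local appearance — not clinical-grade
performance on real endoscopy video.

Three published profiles (`benchmark_suite()`):

* **smoke** — 20 scenes, 64×64 (14/3/3 split); a full run takes well
  under two minutes on one CPU.
* **recovery** — 200 train / 50 test scenes, 96×96, tight boxes. The
  headline benchmark: tiny network, circle initialization, schedule
  [2,2,2,2]. With seed 0 the initial circle targets score mean dice 0.72
  against ground truth; after training, the model's test dice is 0.91.
* **ordering** — 120 train / 30 test scenes at 96×96 with 30% loose
  boxes (padding 0.3) and 10% distractor bars, plus 30 held-out
  mask-labelled scenes on which a small initializer model (12 supervised
  epochs) is trained to feed the prediction/hybrid strategies — its
  predictions are good on clean scenes but unreliable here, so roughly a
  third of the boxes fail the 30% coverage rule and fall back to
  circles; schedule [2,2,2]. These sizes keep the full three-seed
  comparison of circle / hybrid / mixed supervision inside a coffee
  break while still separating the variants.

## Numerical and design choices

* Coordinate convention: pixel (0,0) is the top-left pixel *centre*;
  boxes are continuous, half-open on the max side; "inside" means the
  pixel centre satisfies the box inequalities. One convention everywhere
  prevents off-by-one drift between clipping, rasterization and the ring
  mask.
* Thresholds are strict (`> 0.5`) and shared between initialization,
  refinement and evaluation.
* Boxes are stored on disk by min-corner (`image_id, x_min, y_min,
  box_w, box_h`), the common interchange form; centres are derived.
* Degenerate ring regions (no pixel centre strictly between the radii)
  raise an error rather than silently returning an all-ones mask:
  surfacing a bad annotation beats hiding it.
* **Refresh coverage guard** (`refine_min_coverage`, default 0.3).
  Self-training has a known failure mode when the network starts from
  random weights: early in training the probabilities hover near 0.5,
  thresholding yields a near-empty mask, and accepting it as the new
  target erases the supervision signal — the run then locks into
  predicting background everywhere (we observed exactly this at some
  seeds: final dice 0.0, with every target empty after two iterations).
  Pre-trained encoders largely hide the problem because their first
  predictions are already decisive. The guard reapplies the coverage
  rule the hybrid initializer already uses: a refreshed target covering
  less than 30% of its box is rejected and the image keeps its current
  target until the network becomes decisive there. Rejections are
  per-image; set `refine_min_coverage = 0` for the unguarded refresh
  (an all-negative refreshed target is then allowed).
* Metrics are averaged per image, not pooled over pixels, so averaged
  confusion counts are fractional but still sum to the per-image pixel
  count; dice of two empty masks is 1 by convention.
* An all-negative refined target is allowed (the image then contributes
  only background supervision until a later refresh revives it).
* `evaluate_set()` supports tag filtering (e.g. a histology subset such
  as sessile serrated adenomas) so subgroup evaluation reuses the same
  machinery.

## Limitations

* The refinement loop can only recover contours that are inferable from
  local image appearance; objects indistinguishable from background
  inside the uncertainty band will keep their initializer's shape.
* The literal (squared-offset) ring is retained for fidelity but is not
  useful as a training signal at small image sizes; use the Euclidean
  variant for actual training.
* The CPU network is deliberately small; it is a vehicle for validating
  the training mechanism, not a real-time clinical segmenter.
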