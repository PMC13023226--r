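---
title: "Collaborative multiscale wavelet segmentation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative multiscale wavelet segmentation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cmwnet)
```

## The problem

Leakage lesions in ultra-widefield fluorescein angiography are bright,
irregular, diffuse regions on images of several thousand pixels per side.
Two standard tricks make such images tractable — down-sampling the whole
frame, or cropping it into tiles — and each destroys exactly the
information the other preserves: down-sampling erases small low-contrast
foci, cropping severs the global context that distinguishes a lesion from a
bright vessel segment. The package trains one network *per view* and makes
the views collaborate.

## Model

Both branches share one backbone, a U-Net whose resolution changes are
wavelet transforms rather than pooling:

* **Encoder stage** $i$:
  $F_i = \mathrm{ReLU}(\mathrm{GN}(\mathrm{Conv}_{3\times3}(
  \mathrm{ReLU(GN(Conv_{3\times3}}(F_{i-1})))))$, then a single-level
  orthonormal Haar DWT of $F_i$. All four subbands (LL, LH, HL, HH), stacked
  along channels, feed the next stage, so the down path loses no
  information; $F_i$ itself is stored for the skip path. Channel counts
  double per stage.
* **Bottleneck**: one more double-convolution block without a DWT, so the
  convolutional unit is applied `depth + 1` times (five times at the default
  depth 4).
* **Decoder stage** $j$: a 1×1 convolution reduces channels, the inverse
  DWT doubles resolution (detail subbands zero-filled), the stored $F_j$ is
  **added** (shapes match by construction; interpolation and 1×1 projection
  would align them otherwise), and a double-convolution block refines.
* Head: 1×1 convolution + sigmoid.

The Haar filters use the orthonormal normalization, which makes
$\|x\|^2 = \|LL\|^2 + \|LH\|^2 + \|HL\|^2 + \|HH\|^2$ a testable invariant
and perfect reconstruction exact to machine precision.

Two genuinely open wiring questions were settled as follows, each kept
configurable:

* whether decoder inverse-DWTs receive the encoder's detail subbands or
  zeros: default **zeros** (the skip path routes only the stored feature
  maps, which are added *after* the inverse transform); the alternative is
  `wunet_config(skip_subbands = TRUE)`.
* add vs concatenate at skips: the recurrences say add, so we add.

## Objective and coupling

Per branch: `w_bce*BCE + w_dice*SoftDice + w_tversky*Tversky`. No weights
are published, so all three default to 1. Tversky penalties default to
(0.3, 0.7) — false negatives cost more, matching the clinical cost of
missed leakage — and at (0.5, 0.5) the Tversky term provably collapses to
soft Dice (kept as a test). The smoothing constant defaults to 1e-6.

The branch losses combine as $L_3 = (1-\alpha)L_1 + \alpha L_2$ and the
total objective is $L_3 + \beta L_4$, with $\beta \sim U(0,1)$ drawn once
per optimizer step from a seeded stream. $L_4$ is the mean squared
difference between the bilinearly up-sampled global probability map and the
montaged local maps, restricted to the tiles actually sampled that step; it
is computed on probabilities, not thresholded masks, to stay
differentiable. Both branches receive gradients from the total loss *and*
the global branch is blended toward the local branch after each step
($\theta_G \leftarrow (1-\alpha)\theta_G + \alpha\theta_L$): the published
description both includes $L_1$ in the objective and has the teacher update
the student by EMA, and this is the reading that keeps both statements
true. The branches start from identical seeded initialization
(configurable).

$\alpha$ defaults to 0.3 — the value reported to give the best segmentation
performance in the source study's sweep — and is the single most important
tunable: it simultaneously weights the local branch's loss and the speed at
which the global branch adopts the local branch's weights.

Optimization follows the published recipe exactly: AdamW, lr 0.005, betas
(0.9, 0.999), weight decay 3e-5, AMSGrad off, cosine annealing to 1e-5 with
a 50-epoch period, batches of four images (implemented as gradient
accumulation), evaluation batch 1. "T_max = 50 cycles" is read as one
cosine period of 50 epochs.

## Inference

Global probabilities are bilinearly up-sampled to source resolution; local
probabilities are montaged (the exact inverse of the tiling). The default
final step binarizes both maps at 0.5 and applies **CGNR**: local-mask
background pixels flagged by the global mask are promoted iff an 8-neighbor
is foreground in the local mask. The printed rule does not fix a scan
order; the default is a *simultaneous* single pass (all neighbor reads from
the original base), the only convention that is order-independent. A
fixpoint variant iterates the pass until convergence and is monotonically
larger. Out-of-bounds neighbors count as background. The order of fusion
versus refinement is also unstated in the source; the default refines the
two binarized branch masks directly (matching the refinement figure), and
`fusion_first = TRUE` switches to thresholding the weighted probability
fusion (weight 0.5) before refinement.

## Metrics

DSC, precision and recall from pixel confusion counts (both-empty masks
score 1). HD95 and ASD are computed between *boundary point sets*
(foreground pixels with a background 8-neighbor; the image border counts as
background), symmetric (max of directed 95th percentiles for HD95, pooled
mean for ASD), Euclidean, in pixels. The source paper's printed distance
formulas reference a "central point" and within-set nearest neighbors,
which contradicts its own prose definition of boundary-to-boundary
distances; the prose matches standard practice and is what is implemented.
Empty masks yield the image diagonal as a flagged sentinel.

## Synthetic data

The generator emulates what makes UWFA leakage segmentation hard without
claiming photorealism: an elliptical field of view with radial vignetting
over a dark surround; bright curvilinear vessels (quadratic Bézier tubes)
that are *never* labelled, providing lesion-like confusers; lesions built
as unions of 3–8 jittered discs, Gaussian-blurred, with the mask defined as
the blurred field at or above half its maximum — irregular and fuzzy in
appearance, crisp and analytic as ground truth. Lesion placement is
rejection-sampled so masks never touch the vessel stencil, keeping labels
unambiguous. Additive Gaussian noise, clipped to [0, 1]. Every dataset
contains at least one lesion small enough (< H·W/4096) to vanish under
down-sampling — the regime the collaborative design targets. All
randomness derives from one integer seed with per-case offsets; identical
configurations are byte-identical on disk. The default canvas is
2048×1536 — deliberately not a multiple of 512 so the resize-to-multiple
step is always exercised. Lesion size and contrast distributions are
plausible stand-ins, not calibrated to clinical data: passing tests show
the pipeline recovers lesions of this synthetic phenomenology, not clinical
performance.

## Preprocessing

CLAHE (clip limit 2, 8×8 tiles — unpublished, so configurable) then gamma
0.8 (brightens the dark periphery) then nearest-neighbor resize **up** to
the next multiple of 512. Rounding up rather than down avoids destroying
detail, which is the method's entire concern; nearest-neighbor keeps masks
binary; the operation is idempotent. CLAHE precedes resizing (the published
pipeline figure implies preprocessing comes first). Images with dimensions
not divisible by the CLAHE tile grid are edge-padded for equalization and
cropped back. Augmentation (training only): paired horizontal flips with
probability 0.5, photometric jitter on the image alone (brightness/contrast
±0.2, saturation ±0.2 and hue ±0.05 for RGB), so mask geometry follows
image geometry exactly.

## Scaled-down study conditions

CPU-scale experiments use ten easy synthetic cases: 256×256 canvas, 3
large high-contrast lesions (radius 7–16 % of the canvas, contrast 0.5,
blur σ 2, noise 0.01), 4 vessels; split 6/2/2 (the 60/16/24 proportions of
the source study's 111/29/43 split); backbone depth 3, base channels 8;
both branch inputs at 128 px — half the canvas, preserving the
global-to-tile ratio of the full-scale recipe — with all four
non-overlapping 128 px tiles of each image entering training, as the
full-scale recipe tiles entire images; α = 0.3; 30 epochs. These sizes keep
the full study (including the down-sampling-only ablation trained with the
same seed) within minutes on one CPU core. The down-sampling-only and
crop-only ablations are plain config switches (`mode = "downsample"`,
`mode = "crop"`): single-branch training with EMA off.

### What the scaled study can and cannot show

The scaled experiment demonstrates that the collaborative model trains,
couples, and recovers lesions (held-out Dice well above 0.7 within 30
epochs). It does **not** reproduce the full-scale ablation ordering in
which the collaborative model beats the down-sampling-only baseline. The
reason is structural, and the package's own diagnostics expose it: with a
256 px canvas and 128 px branch inputs, down-sampling is essentially
information-preserving for large high-contrast lesions, so the
down-sampling-only baseline sees everything it needs *plus* full global
context, and scores near its ceiling. Meanwhile the local branch,
tile-blind to context, misclassifies bright vessel segments as leakage
(in our diagnostics roughly 40–50 % of its false-positive pixels lie on
the vessel stencil — precisely the vessel/leakage confusability the
method is motivated by), and the EMA coupling propagates some of that
noise into the global branch. The published ordering arises in the
opposite regime — ultra-high-resolution images whose down-sampling factor
(~6–8x) destroys subtle foci — which cannot be reached simultaneously
with "easy, large, high-contrast lesions trainable in 30 CPU epochs" on a
256 px canvas. The acceptance suite asserts the full-scale ordering
anyway and documents the failure rather than weakening the check; the
acceptance script reports both Dice values and their difference so the
regime effect is visible in numbers.

## Numerical choices

* Binarization threshold 0.5 (unpublished), configurable.
* Area (box-average) resampling implements the global down-sampling — it
  preserves mean intensity exactly — and bilinear resampling implements
  up-sampling and consistency alignment. Both are built as separable
  interpolation-matrix products, which gives the exact adjoint needed to
  backpropagate through the up-sampling (the transpose of the same
  matrices).
* Masks down-sampled for the global target are area-averaged then
  re-thresholded at 0.5.
* He initialization, seeded; group-norm groups default to 8, reduced per
  layer to the largest divisor of the channel count.
* Gradient correctness of the hand-written backward pass (convolutions,
  group norm, wavelet stages, both skip wirings) is enforced by
  finite-difference tests.
* All losses clamp probabilities away from {0, 1} by 1e-7 inside the BCE
  term only.

## Known limitations

* The synthetic generator does not model early/late-phase dynamics,
  device-specific distortion, annotation noise, or peripheral artifacts —
  the documented failure modes of the clinical method (artifacts
  misclassified as leakage, vessel-adjacent over-segmentation) have no
  synthetic counterpart here.
* Training is single-threaded CPU R; the package is a faithful, tested
  reference implementation at desk scale, not a performance tool. Published
  clinical-scale accuracy figures are out of reach by construction (the
  clinical dataset is private).
* Tiling is strictly non-overlapping; no test-time augmentation; no
  uncertainty maps.
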