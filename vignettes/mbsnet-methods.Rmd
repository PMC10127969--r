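---
title: "MBSNet: model, training recipe and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MBSNet: model, training recipe and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbsnet)
```

## The segmentation model

MBSNet addresses binary lesion segmentation — one foreground structure class
against background — in modalities such as dermoscopy, endoscopy, ultrasound,
chest X-ray and MRI. Its premise is that accurate boundaries need *local*
texture detail and *global* shape context simultaneously, and that a network
can stay small if the two are learned by separate, shallow branches rather
than one deep encoder.

**Local branch (L).** Five levels of width 16, 32, 64, 128, 256, one 3×3
convolution (batch norm, ReLU) per level, 2×2 stride-2 max pooling between
levels. Each level is refined by a *parallel residual mixer* (PRM): a
stride-1 window-3 max-pool path sharpened by a 1×1 convolution runs in
parallel with a 1×1 convolution followed by a depthwise 3×3 convolution
(layer normalization over the channel axis at each position, then GELU); the
two paths are concatenated to 2C channels and fused back to C by a 3×3
convolution before a residual addition. Because all PRM components preserve
shape, the block is an exact identity when its learnable tensors are zero —
a property the tests exploit. An SE gate (global average pool →
C → C/4 → C bottleneck → sigmoid) re-weights channels after each PRM.

**Global branch (G).** Three dilated-convolution blocks of width 16, 32, 64
at full, 1/2 and 1/4 resolution, with 2×2 *average* pooling between blocks
(averaging preserves more of the global intensity structure than max
pooling, and stopping at 1/4 scale avoids destroying spatial layout). Each
block is 1×1 → dilated 3×3 → 1×1, all batch norm + ReLU; the middle
convolutions use multi-grid dilation rates r·(1, 2, 4) with r = 2, i.e.
rates (2, 4, 8), so the three receptive fields grow geometrically (a 3×3
kernel at dilation 8 spans 19 pixels). Before each block, the same-level
output of branch L is concatenated and reduced by a 1×1 convolution, so the
global stream is continuously refreshed with local evidence. The final
output passes a spatial attention module (SAM): the channel vector from
global average pooling is squeezed (C → C/4 → C, GELU between), softmaxed
over channels, and used to weight a 1×1 "value" projection of the feature
map; the weighted channel sum is a single spatial context map that is
broadcast-added to all channels, plus a residual. Since the softmax weights
sum to one, a constant value map leaves the input unchanged up to a constant
— another tested invariant.

**Fusion branch (F).** The deepest local features are decoded with two
upsample-and-skip steps (concatenation + 3×3 reduction) down to 64 channels
at 1/4 scale, where they meet the global stream of the same shape. Two
*feature cross-fusion blocks* (FCFB) then climb back to full resolution: at
each stage both streams are upsampled ×2 at halved width, and each output is
the channel-projected bilinear upsample of its own stream **plus** the
conv-upsample of the other stream ("cross-added"). The full-resolution
streams are concatenated and a 1×1 convolution produces one logit channel.
No activation is applied in the network; the sigmoid lives in the loss and
metrics layer for numerical stability.

## Loss, metrics and ranking

Training minimizes the joint loss

$$\mathcal{L} = 0.5\,\mathcal{L}_{\mathrm{bce}} + \mathcal{L}_{\mathrm{dice}},
\qquad
\mathcal{L}_{\mathrm{dice}} = 1 - \frac{2\sum p g + \varepsilon}
{\sum p + \sum g + \varepsilon},$$

with p = sigmoid(logits), binary targets g, and smoothing ε = 1. The BCE
term is evaluated in the logit form, so saturated predictions cannot
overflow. Dice pools all pixels of a batch; its gradient is the exact
analytic derivative of the smoothed ratio.

Evaluation binarizes probabilities at 0.5 (the boundary maps to foreground),
counts per-image confusion tables, and reports IOU, F1, precision, recall,
specificity and G-mean on the 0–100 scale. Conventions for degenerate
images: if prediction and truth are both empty every metric is 100 (the row
is flagged); an empty truth with a non-empty prediction scores IOU = F1 = 0.
A dataset value is the unweighted mean over images (macro); the pooled-pixel
micro average is attached as an attribute because the two can differ
substantially on datasets with very different lesion sizes, and published
comparisons rarely state which was used.

Model comparison uses classic TOPSIS on the models × {F1, IOU, G-mean}
matrix: Euclidean column normalization, equal weights, ideal/anti-ideal
taken over the candidate set, score d⁻/(d⁺+d⁻). All three criteria are
benefits. With candidate-set ideals, a model worst on every criterion scores
exactly 0 and one best on every criterion exactly 1; scores are invariant to
positive rescaling of a criterion and equivariant under row permutation.
Ranks are competition ranks (ties share the smaller rank), and cross-dataset
comparison averages ranks, not scores, because scores are not comparable
across candidate sets.

## Training recipe and its knobs

| parameter | default | notes |
|---|---|---|
| optimizer | Adam, β = (0.9, 0.999), no weight decay | standard for this family |
| learning rate | 0.001 → 0.00001 | cosine annealing per epoch; endpoints exact |
| batch size | 4 | small batches keep batch-norm statistics honest at desk scale |
| epochs | 100 | a knob; overfitting checks in the tests use 150 |
| input size | 320×320 | must be divisible by 16 (four poolings in branch L) |
| augmentation | h/v flips p = 0.5, crop fraction 0.8–1 | applied identically to image and mask |
| loss | 0.5·BCE + Dice, ε = 1 | coefficients fixed |
| selection | validation IOU (F1 selectable) | best checkpoint across epochs is kept |
| evalEvery | 1 | validation cadence; long overfitting runs use 10 to spend time on training rather than re-scoring an unchanging split |

The whole pipeline is seeded: the build seed fixes the Kaiming-uniform
initialization, the training seed fixes shuffling and augmentation, and the
generator seed fixes the data, so two runs with equal seeds produce
identical histories and checkpoints (tested to bit-exactness for the
checkpoint round trip).

## The synthetic data generator

`generateSample()` emulates the geometry shared by single-lesion
segmentation datasets: 1–3 smooth closed blobs (a circle whose radius is
modulated by a low-order random Fourier series, with mild ellipticity),
placed in the central region, brighter than background by a configurable
contrast, with a Gaussian-blurred boundary, additive Gaussian sensor noise,
and optional multiplicative speckle for ultrasound-like texture. Defaults —
one blob, radius 12–30 % of the image side, roughness 0.15, contrast 0.35,
noise σ = 0.05 — were chosen once as a plausible mid-point between the easy
(dermoscopy) and hard (ultrasound) ends of that spectrum. Degenerate draws
(foreground below 0.5 % or above 60 % of the image) are regenerated from a
derived sub-seed, failing after ten attempts.

What the generator deliberately does **not** model: anatomical context and
distractor structures, modality-specific artefacts (hair, specular
highlights, shadowing), multi-scale texture inside the lesion, and
inter-image intensity shifts. Passing the learning smoke test therefore
demonstrates that the architecture, loss, gradients and optimizer function
as a system — not that the network would reach any particular accuracy on
clinical data.

## Numerical choices

* **Convolution kernels** run as single-precision GEMMs (Armadillo) inside a
  double-precision graph: inputs, weights and gradients are converted to
  float per call. This doubles single-core throughput at ~10⁻⁷ relative
  arithmetic error, far below the 10⁻⁵ tolerance at which the kernels are
  checked against a nested-loop oracle. All other ops are double precision.
* **Bilinear resampling** uses half-pixel centers (corners not aligned)
  everywhere — inside the network and in preprocessing — so a single
  documented convention governs all interpolation; nearest-neighbour is used
  for masks, which are re-binarized after every geometric operation.
* **Batch norm**: momentum 0.1, ε = 10⁻⁵, biased batch variance, gain 1 /
  offset 0 at initialization; training mode uses batch statistics, inference
  the running ones. Layer norm in the PRM normalizes over the channel axis
  at each spatial position, matching its depthwise path.
* **Initialization**: Kaiming-uniform for convolution and linear weights,
  uniform ±1/√fan_in biases, drawn from the R RNG under the configuration
  seed.
* **Thresholds and ties**: binarization maps exactly 0.5 to foreground;
  competition ranking gives ties the smaller rank; identical TOPSIS rows
  (zero distance to both ideals) are defined as 0.5 with a warning.
* **MAC accounting** counts convolution and linear layers only
  (C_out·H'·W'·C_in·k²/groups per convolution), ignoring normalization,
  activations and pooling, by instrumenting an actual forward pass — the
  count can therefore never drift from the executed graph.

## Open design points and how they were fixed

Several aspects of this architecture family are under-determined; the
package fixes one consistent reading and documents it:

* **PRM plumbing**: both 1×1 convolutions keep C channels, the concatenation
  has 2C, and the fusing 3×3 maps 2C → C so the residual is well-formed. The
  pooling inside PRM is the shape-preserving stride-1 window-3 kind; the
  resolution-reducing 2×2 pooling sits *between* levels. One depthwise
  convolution is used.
* **Dilated block**: realized as 1×1 → dilated 3×3 → 1×1 (the reading in
  which the outer "standard" convolutions are pointwise); block i of branch
  G uses rate 2·multiGrid[i].
* **SAM wiring**: of the possible query/key/value assignments, the one
  implemented is the only one we found in which every shape closes without
  extra projections: softmax over channels of a squeezed global descriptor,
  applied to a 1×1 value map, broadcast-added with a residual. Its cost is a
  few thousand parameters and ~0.03 G MACs at 320×320 — attention as a
  near-free refinement.
* **SE reduction 4**: the narrowest level has 16 channels; a conventional
  reduction of 16 would collapse it to a single unit.
* **Branch-G widths 16/32/64** mirror the first three local levels so the
  level-wise fusion needs only concatenation + 1×1 reduction; decoder widths
  follow the usual U-shape halving, and the two FCFB stages halve 64 → 32 →
  16 so that full resolution is reached in exactly two doublings.
* **Upsampled convolution blocks** convolve first and interpolate second;
  with the convolution at the coarse grid the block is cheaper, and the
  bilinear kernel after it suppresses checkerboard artefacts.

With these choices the default network counts 3 059 197 parameters and
5.87 G MACs for a 320×320 input (recomputed by `scripts/acceptance.R` and
printed by `show()`); the complexity grows strictly along the ablation chain
plain → +PRM → +SE → +SAM, and halving the input side divides every
convolution's MACs by four. Published complexity figures for this
architecture family are somewhat higher than this reconstruction, which is
consistent with the width and plumbing choices above being the main free
variables; the tests therefore pin the *structure* (monotonicity, scaling,
per-layer formulas) rather than any single total.

## Problem sizes used by the test suite

Unit tests exercise blocks at 5×5–64×64 and the full network at 32×32–128×128
with batches of 1–4; the complexity checks run a single 320×320 forward
pass. The learning smoke test trains on eight 128×128 synthetic images
(validation split = training split) for 150 epochs at batch size 4,
validating every 10 epochs — chosen as the smallest workload on which
"the system learns" is demonstrated by a training IOU above 80.

## Known limitations

* Single foreground class, single logit head; no multi-class support.
* CPU only, one thread; the engine is written for clarity and testability,
  not to compete with framework kernels.
* The checkpoint format is R serialization (RDS) — portable across platforms
  running R, but not a cross-language exchange format.
* Metrics are overlap-based only; boundary-distance measures (Hausdorff,
  ASSD) are out of scope.
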