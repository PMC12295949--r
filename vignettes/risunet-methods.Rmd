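---
title: "Methods: 2.5D liver tumor segmentation with Res-Inception-SE U-Nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2.5D liver tumor segmentation with Res-Inception-SE U-Nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices behind
the package, in the spirit of a methods section: what is computed, which
decisions were genuinely open, and what the synthetic tests do and do not
demonstrate.

## The 2.5D input model

A CT scan is a volume $V \in \mathbb{R}^{H \times W \times D}$ with per-axis
voxel spacing in mm. For a center slice $t$ the model input is the stack of
$n$ consecutive slices
$X_t = (I_{t-\lfloor n/2 \rfloor}, \dots, I_t, \dots, I_{t+\lfloor n/2
\rfloor})$, fed to a 2D network as $n$ input channels; the first convolution
mixes the slices as $\sum_{i=1}^{n} W_i * I_{t+i-\lceil n/2 \rceil} + b$.
$n$ must be odd so the stack is symmetric around the supervised center
slice. Slice indices are 1-based throughout (the R convention); channels
referring to slices outside $[1, D]$ are zero-filled planes. Supervision
always targets the center slice's mask only.

## Preprocessing pipeline

Each slice passes through four deterministic steps, in this order:

1. **Hounsfield windowing** — clamp to $[-200, 200]$ HU. This is the
   operative intensity range; a display window/level of 40/400 would give
   $[-160, 240]$, but the clamp range is what the pipeline applies, and the
   window/level is retained only as metadata.
2. **Center crop** — $448 \times 448$ from $512 \times 512$ by default,
   removing air background. For odd margins the extra discarded pixel is
   taken from the high-index side; this is an arbitrary but fixed, testable
   convention.
3. **Histogram equalization** — global (whole-slice), 256 equal-width bins
   over the window range, each pixel mapped to the empirical CDF of its bin.
   This is the simplest standard reading of "histogram equalization";
   adaptive variants (CLAHE) were deliberately not used. Equalization after
   cropping (rather than before) is a convention; both orders are
   reasonable, and the chosen one equalizes exactly the pixels the model
   sees.
4. **Normalization** — min–max rescale to $[0, 1]$ per slice; a constant
   slice maps to zeros to avoid division by zero.

For training, slices without tumor are dropped (`keep_only_tumor_slices`);
at inference every slice is segmented — the filter is a training-set
operation only. The train/validation/test split defaults to 8:2:2
*normalized* (i.e. 2/3, 1/6, 1/6): the ratio is taken at face value even
though it sums to 12 parts; users who intended 8:1:1 can pass any fractions.

## Architecture

The network is a five-level encoder–decoder ("five" counts the bottleneck;
there are four $2{\times}2$ max-poolings, so spatial dims must be divisible
by 16). Every convolution stage is a Res-Inception-SE block:

* **F1** $1{\times}1$ conv; **F2** $3{\times}3$ conv of F1; **F3** two
  further $3{\times}3$ convs (three serial $3{\times}3$s total — a
  $7{\times}7$ receptive field at lower cost, which the tests verify by a
  gradient-support probe); **F4** a $3{\times}3$ stride-1 max-pool of F3
  followed by a $3{\times}3$ conv. The exact composition of F4 is the main
  architectural judgment call in the package: "pool + conv on F3" enlarges
  the receptive field further without changing resolution, which is the
  role this branch plays.
* The four branches are concatenated (widths $\lfloor C/4 \rfloor$ each for
  F2–F4, remainder to F1) and fused by a $1{\times}1$ conv.
* **SE attention**: global average pool per channel, bottleneck
  $C \to \max(C/r, 1) \to C$ with ReLU then sigmoid, reweighting the fused
  features. $r = 16$ is the conventional default.
* A $1{\times}1$ **residual projection** of the block input is added to the
  gated features.

Each conv is conv → batch norm → ReLU (the standard U-Net-variant recipe);
convolutions under batch norm are bias-free, since BN's shift makes a bias
redundant and its gradient identically zero. Decoder levels upsample with
$2{\times}2$ stride-2 transposed convolutions and concatenate the encoder
skip feature before the block. The final $1{\times}1$ conv plus sigmoid
yields per-pixel tumor probabilities.

**Channel plan and the parameter budget.** The per-level widths are not
fully determined by a doubling rule once the parameter budget is fixed at
15.02 M: with strict doubling the count jumps by roughly 0.4 M per unit of
base width near 15 M, so no base width lands on that budget. The package
therefore freezes a *reference plan* (80, 156, 312, 616, 1220) — doubling
slightly trimmed at levels 2, 3 and 5 — whose exact count is 15,019,033,
i.e. 15.02 M at two decimals. `count_parameters()` computes the budget
directly from the configuration; the test suite checks it equals the sum of
the actually allocated tensors.

**Initialization.** Kaiming-uniform (fan-in) for convolution weights, zeros
for biases, unit BN scales. The SE squeeze weights are drawn non-negative:
the pooled descriptor of a post-ReLU map is non-negative, so this keeps
every bottleneck unit active at initialization and guarantees gradient flow
through the gate even for width-1 bottlenecks.

## Loss

$L = \alpha L_{\text{Dice}} + \beta L_{\text{BCE}}$ with $\alpha = \beta =
1$ by default — the weights are exposed but no evidence distinguishes other
settings. Soft Dice is computed over the whole batch (not per-sample) with
smoothing $10^{-5}$, which keeps empty-target batches finite and stable;
plain sums are used in the denominator (not squared). BCE is the mean over
voxels with probabilities clamped at $10^{-7}$. Analytic gradients of both
terms are implemented and verified against central differences at $10^{-4}$.

## Metrics

DPC and VOE are pure overlap counts; RAVD uses the absolute convention
$||B|-|A||/|A|$ — a signed variant $(|B|-|A|)/|A|$ also circulates, but the
quantity is named *absolute* volume difference and conventionally reported
as non-negative with "lower is better", so the absolute value is the
consistent reading.
Surface voxels are foreground voxels with a background 6-neighbor, with the
volume boundary counting as background (cavity walls are surface).
Coordinates are scaled to mm by the voxel spacing; nearest-surface distances
use an exact anisotropic Euclidean distance transform (lower-envelope
parabola algorithm per axis), which the tests verify against $O(|S_A||S_B|)$
all-pairs brute force to $10^{-9}$ mm on 200 random mask pairs. Empty-mask
policy: $\mathrm{DPC}(\varnothing,\varnothing)=1$,
$\mathrm{VOE}(\varnothing,\varnothing)=0$; RAVD and the surface metrics are
undefined for empty reference/masks and reported as `NA`, excluded from
aggregates. Per-case metrics are averaged across cases (per-volume then
average, the standard reporting style for liver benchmarks), not pooled over
voxels.

## Training protocol

Adam (lr 0.003, $\beta_1 = 0.9$, $\beta_2 = 0.999$), batch size 8, 150
epochs, seed 39. "Iterations" is read as epochs, consistent with multi-hour
training times on the clinical dataset; `max_steps` additionally caps total
optimizer steps for small-budget runs. Augmentation (off by default,
enabled per flag) applies identical transforms to all stack channels and the
mask: horizontal/vertical flips with probability 1/2 and random crops of
side fraction uniform in $[0.8, 1]$ resized back bilinearly
(nearest-neighbor for masks). Validation data are never augmented. Model
selection keeps the weights with the best validation DPC (mean slice-wise
Dice); the final weights are also retained. Inference thresholds the
sigmoid output at 0.5 and uncrops predictions by zero-padding back to the
original in-plane size.

Determinism: everything draws from R's RNG under the configured seed, and
the arithmetic is single-threaded, so repeated runs give bit-identical loss
curves, checkpoints and metric CSVs on the same platform.

## The phantom generator

Phantoms emulate the *data regime* of low-contrast abdominal CT, not
anatomy: an ellipsoidal liver (semi-axes drawn per case) on a darker
background, spherical tumors placed fully inside the liver, per-region
Gaussian intensities (background $-100 \pm 20$, liver $60 \pm 10$, tumor
$45 \pm 10$ HU — a 15 HU mean contrast), in-plane Gaussian smoothing
($\sigma = 1$ voxel) and additive noise (sd 5 HU). Default geometry is
$64 \times 64 \times 24$ voxels at $0.8 \times 0.8 \times 1.5$ mm — chosen
as the small end of realistic abdominal acquisitions so that end-to-end
training runs in minutes on one CPU; the trainability checks use 12 cases,
an 8:2:2 split and 200 optimizer steps at base width 8. Each case has its
own RNG stream derived from (master seed, case index), so cases are
independently reproducible.

What passing phantom tests show: the pipeline is wired correctly end to end
— gradients flow, the optimizer reduces the loss, held-out Dice is well
above chance, masks stay aligned through every transform. What they do not
show: clinical performance. Phantoms lack the texture, vasculature, organ
neighbors, boundary ambiguity and annotation noise of real CT, and a model
that segments bright-ish ellipsoids is not evidence about hepatic lesions.

## Numerical choices and limitations

* Batch norm uses $\epsilon = 10^{-5}$ and running-stat momentum 0.1;
  training-mode statistics are per-batch, inference uses running averages.
* Max-pooling ties break toward the first scanned element (lowest linear
  index), fixed and deterministic.
* The distance transform uses a large finite sentinel ($10^{300}$) rather
  than IEEE infinity so empty scan lines remain well defined.
* Training is single-threaded CPU; the full-size 15 M-parameter model is
  buildable and countable everywhere, but training it at $448 \times 448$
  is only practical with far more compute than the test suite assumes —
  the suite trains reduced-width models at reduced resolution.
* DICOM assembly, isotropic resampling, multi-organ labels, 3D variants and
  alternative Inception blocks are out of scope; the block interface would
  admit swap-in variants.
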