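---
title: "Fine-root segmentation with an attention U-Net: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-root segmentation with an attention U-Net: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rhizotrons and minirhizotrons photograph roots in situ through a
transparent window, producing time series of large scans in which fine
roots (< 2 mm diameter) appear as thin, branching, often low-contrast
strands against heterogeneous soil. Manual tracing of such images takes
hours per scan; `rhizoseg` automates the segmentation and converts the
resulting masks into root-length estimates that can be compared,
per root order, with manual line-intersect measurements.

## Data pipeline

**Patching.** Annotated scans are standardized (the reference protocol uses
1275×1755 px) and tiled by a sliding window (default 512 px window, 256 px
stride). Window origins advance by the stride until the image is covered;
partial edge windows are filled with black. The per-axis window count is
`ceil(max(dim − patch, 0)/stride) + 1`; this is the only edge rule
consistent with 82 scans of 1275×1755 yielding 1968 patches, so it is
adopted. Patches are split 7:2:1 by `floor`/`floor`/remainder — the unique
rounding that turns 1968 into 1377/393/198 — with the split seed recorded in
the run configuration. The split operates at patch level.

**Preprocessing.** Inputs are resized (bilinear, half-pixel-center
convention), converted RGB→HSV (hue separates pale roots from brown soil
better than raw RGB), scaled to [0, 1] and reordered channel-first. Masks
are normalized and thresholded at 0.5 so anti-aliased gray edges never
reach the loss; a channel dimension is prepended. The stated protocol
mentions both 256 px (preprocessing) and 512 px (training) inputs without
reconciling them; input size is therefore a configuration field
(`input.size`), defaulting to 256, and 64 in the CPU test profile.

**Augmentation.** Four augmentations fire independently, each with
probability 0.3: color jitter (brightness/contrast/saturation factors
uniform in [0.5, 1.5], applied in RGB before HSV conversion — the order is
our choice, the protocol leaves it unstated), square random crop with area
fraction uniform in [0.2, 1] followed by resize, rotation uniform in ±90°
(corners filled with black, consistent with patch padding), and a flip
(horizontal or vertical with equal probability when the flip fires; the
protocol says only "fixed probability"). Geometric transforms use bilinear
sampling for the image and nearest-neighbour plus re-thresholding for the
mask, so masks stay strictly binary. With probability 0.3 per augmentation,
the chance a sample passes through untouched is 0.7⁴ ≈ 0.24, which the test
suite verifies by Monte Carlo.

## Architecture

The encoder is four DoubleConv stages (3×3 conv → batch norm → ReLU, twice)
with 2×2 max pooling between them, then a bottleneck DoubleConv; channel
widths double per stage (64…512, bottleneck 1024 at full scale; 8…64,
bottleneck 128 in the test profile). After every DoubleConv — including
the bottleneck — the configured attention block is applied:

- **CBAM**: channel gate `Mc = σ(MLP(avg) + MLP(max))` with a shared
  two-layer bottleneck MLP (reduction ratio r, default 16, 4 at test
  scale), then spatial gate `Ms = σ(conv7×7([mean_c; max_c]))`, applied
  sequentially.
- **SE**: channel gate only, from the average-pooled descriptor.
- **none**: plain DoubleConv (the original U-Net building block).

The decoder upsamples bilinearly (align-corners = false), aligns channels
with a 1×1 convolution (E), and fuses with the encoder skip (S) either by
concatenation (original U-Net) or by **UpAdd**: `U = DoubleConv((S+E) ⊙ W)`.
The attention weight W is computed on `concat(S, E)`: its 2C-channel gate
is reduced to C channels by a learned 1×1 convolution. How the 2C-channel
attention output should act on the C-channel sum is genuinely
underdetermined; we chose a learned reduction followed by a sigmoid (so the
modulation stays a (0,1) gate), and with CBAM the spatial gate from the
concatenated map multiplies in as well. With `attention = "none"` the
fusion is the bare sum — matching the ablation grid in which "UpAdd without
attention" is plain additive fusion. The head is a 1×1 convolution to one
channel plus a sigmoid, so the network emits probabilities and the losses
consume probabilities directly.

Inputs must have spatial dimensions divisible by 16 (four poolings); the
forward pass refuses others explicitly rather than padding silently.

## Loss

`L = w1·L_focal + w2·L_dice + w3·L_edge` with weights 0.4/0.4/0.2.
The focal term is the α-balanced focal generalization of binary
cross-entropy (α = 0.9, γ = 2.5), mean-reduced; despite the historical
name of the combined loss there is no separate plain-BCE term in the
stated formula, so an optional BCE weight exists but defaults to 0. Dice
is computed on global sums over the batch with smoothing 1. The edge term
is mean BCE restricted to the Sobel support of the ground-truth mask
dilated by 1 px (0 when the mask is constant); Sobel uses replicate
padding so constant masks and borders contribute no spurious edges.
Probabilities are clamped to `[1e-7, 1 − 1e-7]` inside logarithms, which
keeps all gradients finite at p ∈ {0, 1}. Each component returns its
analytic gradient with respect to p; the test suite checks all of them
against central differences.

## Training

AdamW (decoupled weight decay 1e-4, β = (0.9, 0.999), lr 1e-4 at full
scale) with cosine annealing stepped once per epoch
(`lr(t) = eta_min + ½(lr0 − eta_min)(1 + cos(πt/T_max))`, `T_max` = the
epoch count, `eta_min = 0` — our default, the protocol is silent). No
early stopping or gradient clipping. Every epoch the validation set is
swept over thresholds 0.1…0.9 and the checkpoint with the best validation
mIoU is retained alongside the final one. Transfer learning loads all
weights from a checkpoint, freezes nothing, and starts a fresh optimizer
(whether the original experiments reused optimizer state is unknowable
from the text; a fresh optimizer is the conservative choice). Checkpoints
are single RDS archives carrying a format version, the weights, batch-norm
running moments, the architecture configuration and training metadata;
mismatched architectures are rejected with the differing fields listed.

Because no tensor framework exists on this R stack, the network runs on a
package-internal reverse-mode autodiff over `(C, H, W, N)` arrays. The
layout makes per-channel broadcasts free (R recycles a length-C vector
over the first dimension) and turns convolution into im2col packing (C++)
plus BLAS matrix products. Batch norm uses biased variance for
normalization and for the running moments (momentum 0.1, eps 1e-5);
inference mode uses running statistics and is deterministic. The whole
graph is verified against numerical differentiation in the test suite.
The tiny profile (8–64 channels, 64 px inputs, batch 8, lr 3e-3, 200
steps) exists so that an overfitting run — the standard sanity check that
the gradients and optimizer actually work — completes in ~6 minutes on one
CPU.

## Evaluation

Root is the positive class. IoU, precision, recall and F1 come from pixel
confusion counts; background metrics swap class roles; means are
unweighted two-class averages. Counts are accumulated over the whole split
before metrics are computed (micro aggregation — the alternative,
per-image macro averaging, is available but not the default; the reference
tables do not say which was used). A ratio with a zero denominator is 1
when every count in its formula is zero (empty-empty agreement) and 0
otherwise. Threshold ties go to the smallest threshold. The
"exceeds by k times" comparisons between root F1 scores are
`(a − b)/b` truncated toward zero at two decimals, which reproduces the
published 1.32/1.45/1.26 from the published F1 values.

## Root length and agreement

Masks are thinned to 1-px skeletons by vectorised Zhang–Suen thinning
(no morphology package on this stack provides it). Length sums adjacency
steps — 1 orthogonal, √2 diagonal, with diagonal steps suppressed when an
orthogonal two-step path covers them — plus, per skeleton endpoint, the
distance to the nearest background pixel of the original mask. That last
term compensates the branch shortening (≈ half the local stroke width)
that every thinning algorithm produces; on a 100×3 px bar the measure
returns 100.0, and on a 50-step diagonal stroke it is within 2 % of 50√2.
Per-order classification of predicted roots is deliberately not
implemented: the reference material gives no procedure for deriving root
orders from a segmentation mask, so the agreement statistics consume
per-order length tables as input, and only total length is computed from
masks by this package.

Agreement is Pearson's r with the two-sided p-value from the exact t
distribution (n − 2 df), computed separately for total length and root
orders 1–3, with Bonferroni correction over the m = 4 comparisons (both
raw and adjusted significance are reported). r is invariant to the mm/px
unit mismatch between manual and segmented lengths.

A note on the packaged reference tables: recomputing from the printed
per-image values gives r = 0.719 (r² = 0.518, p = 0.019) for total length
and r = −0.106 for second-order roots, while the published summary states
0.715 (0.512, 0.020) and 0.106. The published correlations were evidently
computed from unrounded source data, and the second-order value was
printed without its sign (its published r² = 0.011 and p = 0.771 match the
signed computation). The acceptance suite asserts the published values as
printed and documents these two expectations as irreproducible from the
printed table; the module tests assert the values the table actually
yields.

## Synthetic data

The generator emulates what makes this imagery hard: brownish backgrounds
built from three octaves of low-frequency value noise plus per-pixel
speckle; thin (1–5 px) random-walk root strokes with stochastic branching
(branch probability 0.02 per step, branch angles from a bounded normal
around the parent direction, width decreasing by 1 px per branch order);
and a configurable foreground–background contrast gap (default 0.35, 0.45
in the test profile where quick convergence matters). Strokes are
rasterized without anti-aliasing so the mask is bit-exactly the painted
pixel set; only the image side gets mild intensity variation. Everything
is a pure function of the configuration (same seed, same bytes), and
datasets regenerate identically from their manifest seeds.

What a green test on this data does establish: the architecture trains,
the losses and gradients are correct, the pipeline is reproducible, and
lengths/metrics are computed correctly. What it does not establish: field
accuracy on real larch rhizotron scans — real soil texture, illumination
drift, occlusion and annotation noise are not modelled, and the published
full-scale metric tables are not reproducible without the original
(non-public) dataset and GPU-scale training. The full-scale profile
(batch 16, 80 epochs, 512 px) ships in the configuration but is not
exercised by tests.

## Known limitations

- The full-scale accuracy tables are out of desk-scale reach (data not
  public); the package substitutes property-based checks (oracle-verified
  losses/metrics, ablation-grid construction, overfitting and
  transfer-learning warm-start properties).
- Root-order topology reconstruction, diameter estimation, and physical
  calibration (mm/px) are out of scope.
- TIFF input is not supported (no TIFF reader on this stack); PNG, JPEG
  and text PNM are.
- Training is single-threaded CPU; full-scale training is impractical
  here by design.
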