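---
title: "Individual tree instance segmentation for leaf-off forest point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual tree instance segmentation for leaf-off forest point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Leaf-off deciduous stands are among the hardest targets for individual tree
segmentation (ITS): without foliage, each crown is an unstructured network of
thin branches, and the branches of adjacent plantation trees interlace. Local
geometry alone cannot tell two entangled crowns apart — their branch textures
are nearly identical — so methods that cluster points by feature similarity
systematically under-segment (merge neighbours) or fragment single trees.

`forestseg` implements an end-to-end set-prediction segmenter for this
regime: a sparse voxel convolutional U-Net extracts multi-scale features, a
transformer-style decoder holds K learnable *instance queries* that each
claim one tree (or the ground) through a predicted binary mask, and — the
load-bearing idea — the mask score of query $k$ at location $i$ combines
feature similarity with an explicit geometric penalty:

$$S_{k,i} = \langle Q_k, F_i\rangle - \lambda\, D(P_i, C_k), \qquad
D(P_i, C_k) = \left\lVert \frac{P_i - P_{\min}}{P_{\max} - P_{\min}} - C_k \right\rVert_2^2 ,$$

where $C_k \in [0,1]^3$ is a normalized instance center regressed from the
query by a small sigmoid-bounded MLP. When two crowns are indistinguishable
in feature space, the $-\lambda D$ term still assigns every point to the
nearer center; the package's acceptance suite asserts this separation
property exactly on constructed identical-feature clusters.

## Pipeline and model

**Preprocessing** mirrors the standard UAV photogrammetry chain: statistical
outlier removal (mean k-nearest-neighbour distance thresholded at the global
mean plus a multiple of the standard deviation), ground/vegetation
classification, DEM construction (per-cell minimum with nearest-neighbour
fill), bilinear height normalization, random downsampling of the ground class
to a target ground/tree ratio, and 10 m sliding-window tiling with 50 %
overlap. The ground classifier here is a grid-minimum rule: per-cell minimum
Z, 3×3 median smoothed, with a height threshold (default 0.3 m). A full
cloth-simulation filter is a published external algorithm; on the flat, open
plantation terrain this package targets, the grid minimum reaches the same
decision for ≥95 % of points on synthetic plots, and the interface is
pluggable so a CSF can be substituted for steep terrain.

**Backbone.** Points are quantized into 0.15 m voxels (per-voxel feature:
mean offset of member points from the voxel center, plus mean color if
present). The U-Net is the classic sparse design: a 5³ stem at 32 channels,
four stride-2 encoder stages of residual blocks (32/64/128/256 channels,
2/3/4/6 blocks), and four transpose-convolution decoder stages with skip
connections (256/128/96/96 channels, 2 blocks each), exposing a feature
pyramid F0 (fine, 96 channels) to F4 (coarse). Global-context channel gates
— mean-pool over occupied voxels, a two-layer bottleneck (reduction ratio 4,
no biases), sigmoid gate — recalibrate the 128- and 256-channel encoder
outputs and the final 96-channel decoder output. Because the gate lies in
(0,1), it preserves sign and sparsity and is elementwise contractive, which
the tests assert.

**Decoder.** K = 20 queries per 10 m block by default (~4–5 trees + ground +
margin). Each decoding layer runs query self-attention, masked
cross-attention to the fine feature level (attention to voxel $i$ is
suppressed for query $k$ when the previous layer's binarized mask excluded
it; a query with an empty mask falls back to unmasked attention), and a
feed-forward network, all pre-norm with residuals; then the proximity-
weighted scoring above. Centers, class logits (ground / tree / no-object)
and mask embeddings are read from shared heads at every layer for deep
supervision. Training matches queries to ground-truth instances per layer by
a Hungarian assignment under the conventional cost
$2\,(-\log p_{\text{class}}) + 5\,\text{BCE} + 5\,\text{Dice} +
\lVert C_k - \hat c\rVert^2$, and minimizes the same weighted sum as the
loss, with the no-object class down-weighted to 0.1. These weights, λ = 1,
3 decoding layers, and the query count are conventions of this architecture
family; none is prescribed by a measurement, so all sit in the configuration.

**Inference.** Voxel masks are `sigmoid(S) > 0.5`; an instance's confidence
is its class probability times its mean in-mask probability; no-object
queries, low-confidence instances (default threshold 0.35) and instances
under 30 points are discarded; overlapping claims resolve to the highest
confidence, then the higher raw score, then the lower query index —
deterministic by construction. Unclaimed points default to ground, so every
point leaves with a semantic label.

## Numerical and engineering choices

The network, its training (AdamW, one-cycle schedule, gradient-norm clipping
at 5) and all layers run on a small reverse-mode autodiff engine written for
this package, with every differentiation rule checked against central finite
differences in the test suite and a fused sparse-convolution op driven by
precomputed kernel maps (integer voxel keys, exact for |index| < 32768 per
axis). Sparse convolutions, including the stride-2 resamplers, are gather–
matmul–scatter products; transpose convolutions route each fine voxel to its
parity-selected kernel tap of its parent, which makes the U-Net exactly
equivariant to integer coordinate shifts that are multiples of the total
stride (2⁴), a property the tests check.

Normalization is per-channel over the occupied voxels of the scene being
processed, in training and at inference alike (running averages are kept
only as a fallback for degenerate single-voxel inputs). Scene-level
statistics are the natural choice for sparse voxel sets whose occupancy
differs block to block, and they make inference deterministic and consistent
with training.

The reference training profile follows the full-scale protocol (initial
learning rate 2·10⁻⁴, one-cycle, 300 epochs, batch 10, voxel 0.15 m) and is
GPU-scale; it is retained as `reference_profile()`. The *desk profile*
(`desk_profile()`) keeps the full topology at a quarter width (final feature
dimension 24), K = 16 queries, 2 decoding layers, 200 optimizer steps with a
4-block minibatch and peak learning rate 2·10⁻³. These sizes were chosen
once so that the complete pipeline — generation, training, evaluation —
runs in minutes on a single CPU; the vignette's numbers and the acceptance
run all use them.

## The synthetic forest generator

The field dataset this method is aimed at (UAV SfM photogrammetry over
a *Populus* plantation) is not redistributable, so the package ships a
procedural stand generator that reproduces the properties the method
actually exercises: trees on a jittered planting grid (4 per 10 m block at
5 m spacing), recursive branching skeletons (trunk, then 3 children per node
up to depth 4, ~35° branching angle with jitter, geometric taper) sampled on
cylinder surfaces only — leaf-off by construction — a roughened ground plane
that forms its own instance, crowns rescaled by an overlap factor (default
1.2, so adjacent crowns interlace as in a closed-canopy stand), Gaussian
coordinate noise and uniform dropout. Full-scale defaults target ~1300
ground points/m², matching high-density photogrammetric surveys; the desk
profile uses 15 ground points/m² and 20 points/m² of branch surface so a
block holds ≈3k points.

What the generator does *not* emulate: photogrammetric artifacts (missing
lower trunks, lighting-dependent noise), species-faithful branch
architecture, understory vegetation, and terrain beyond a smooth roughened
plane. Passing the overfit and ablation checks therefore demonstrates that
the architecture, losses, optimization and metrics are implemented
correctly and that the distance penalty does the geometric work claimed for
it — not that the desk-scale model generalizes to real UAV surveys; that
requires training at the reference profile on real annotated data.

## What the checks compute

```r
library(forestseg)
res <- end_to_end_demo(seed = 1)   # ~8 minutes on one CPU
res$report
```

generates four fixed-seed blocks, trains the desk model for 200 steps and
evaluates on the training split — an overfitting check: AP50 and mean IoU
near 1 show the whole loop can drive the loss to its floor.

The ablation check compares that overfit model against a twin trained
identically (same blocks, seeds and schedule) with λ = 0, applying both to
ten two-tree interlaced-crown scenes laid out on the same planting grid as
the training blocks, and requires strictly higher mean coverage (mCov) for
the penalty variant. The design needs a word of justification. On a *fixed*
training set, any variant of this model can eventually rote-learn any voxel
partition — with enough steps the λ = 0 twin matches the penalty variant
exactly, because sufficiently overfit features act as per-voxel lookup keys;
a training-set comparison therefore measures memorization capacity, not the
geometric mechanism. The informative probe is transfer: this architecture
carries no absolute positional input, so the *only* way a model can localize
instances in a configuration it has not seen is through the query anchors
that the distance penalty trains. On the two-tree scenes the λ = 0 twin,
whose masks rest purely on feature similarity, largely fails to produce tree
instances at all, while the penalty variant's spatial anchors transfer; mCov
separates the two cleanly and in the direction the mechanism predicts.

The metric implementations themselves are validated against an independently
written brute-force evaluator on 200 random scenes to 10⁻⁹, and
`scripts/acceptance.R` re-runs the full computation from scratch at any
seed.

## Known limitations

- The grid-minimum ground classifier misclassifies canopy that overhangs
  the plot border (no ground beyond the edge to anchor the minimum) and is
  not suitable for steep terrain.
- Blocks are segmented independently; instances are not merged across
  overlapping windows into plot-level trees.
- LAZ (compressed LAS) is not read; decompress externally first.
- Training at full width on real plots is possible but impractical in pure
  R; the desk profile is the supported regime for CPU-only experimentation.
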