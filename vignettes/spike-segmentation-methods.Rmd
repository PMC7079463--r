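---
title: "Two-stage spike segmentation and counting: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage spike segmentation and counting: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeseg)
```

## The problem

Wheat spikes (ears) are the grain-bearing organs of the plant; counting
them and measuring their pixel area on cabinet-style RGB images of single
plants is a routine phenotyping task. Spikes are small, textured, partly
occluded structures on a plant that is mostly stem and leaf, so whole-image
segmentation tends to wash them out. `spikeseg` implements a two-stage
encoder--decoder approach:

1. **LPNet** (local patch network) segments overlapping square tiles of the
   image, learning spike texture and colour at patch scale;
2. the per-tile probability maps are merged back into one full-size map;
3. **GMRNet** (global mask refinement network) takes that merged map,
   resized to its input size, and refines it with whole-plant context;
4. the refined mask is thresholded, and spikes are counted per plant as the
   **maximum** flood-fill object count over three side views (0°, 120°,
   240°), because no single view shows every spike.

## Architecture

Both networks share the same encoder/decoder skeleton. Each of the three
encoder blocks is two 3×3 stride-1 convolutions (each followed by ReLU and
batch normalisation) and a 2×2 stride-2 max-pool; the channel widths at the
reference scale are 16, 64, 128. Each decoder block mirrors one encoder
block: a 3×3 transpose convolution that doubles the spatial size, a
concatenation with the pre-pool encoder feature map of the matching
resolution, and two 3×3 convolutions (ReLU + batch norm), with widths 128,
64, 16. A final 3×3 convolution to one channel with a sigmoid produces the
spike-probability map.

LPNet additionally carries a bottleneck of **three stacked hourglasses**
with one scale-up (nearest-neighbour ×2) after the first and one scale-down
(2×2 max-pool) after the second, so the three hourglasses run at 1/8, 1/4
and 1/8 of the patch resolution. An hourglass is a symmetric
residual-module pyramid: four residual modules with 2×2 max-pools going
down, four coming up with nearest-neighbour upsampling, and three skip
branches, each passing through its own residual module before element-wise
addition. A residual module is the classic bottleneck block 1×1 → 3×3 → 1×1
with widths (C, C, 2C) and an identity or 1×1-projection skip; a final 1×1
projection returns the hourglass output to C channels so that its input and
output shapes match exactly.

`shape_trace()` reproduces this arithmetic without weights and is tested
cell-by-cell against the reference layer tables; `count_parameters()` is a
closed form over the same layer enumeration and is tested to equal the
parameter count of the built model.

Three printed details of the reference description cannot hold literally,
and we resolve them the only way the surrounding shape tables allow:

* a transpose convolution with "padding 1 and stride 1" cannot double
  32 → 64; we use stride 2, realised as zero-insertion followed by a 3×3
  stride-1 convolution, which reproduces the tabulated doubling exactly;
* a "3×3×1 convolution with softmax" is degenerate on one channel; a
  one-channel sigmoid is the mathematically equivalent head (it equals a
  two-channel softmax);
* the hourglass interior width is stated ambiguously (128 vs 256); we keep
  the printed residual-module widths (C, C, 2C) internally and project back
  to C at the hourglass output, which satisfies the tabulated I/O shapes.

## The network engine

No deep-learning framework is part of this package's dependency set; the
networks are the package's core, so the forward/backward machinery is
implemented here directly: a small reverse-mode autodiff tape over batched
arrays in channels-first layout `[C, H, W, N]`, with 3×3 convolutions
realised as nine shifted channel matmuls (BLAS), batch normalisation with
running statistics, 2×2 max-pooling with first-entry tie-breaking, and Adam.
Analytic gradients are verified against central finite differences through
both full architectures in the test suite (relative error < 1e-4 on the
pool-tie-free path; < 1e-3 through the hourglasses, where max-pool ties at
ReLU zeros make the loss only piecewise smooth). He-normal initialisation
is drawn reproducibly from a seed without touching the global RNG stream.

## Tiling and merging

`plan_grid()` places `patch_size`-square tiles every `step` pixels, with a
final clamped offset flush with the border when the step does not divide
evenly; "100-pixel overlapping patches of size 256" is interpreted as
step = 100 (overlap 156), the only reading that yields the reference
15 × 12 = 180 tiles on a 1656 × 1356 image. Overlapping predictions are
combined by the arithmetic **mean** (a `max` rule is available): averaging
is deterministic, order-independent, damps tile-seam artifacts, and makes
extract → merge an exact identity, which the suite tests as a property.
How overlapping tile predictions should be reconciled is not specified by
the reference description; the mean is this package's choice.

## Training procedure

Training is two-stage and modular. Stage 1 trains LPNet on image tiles
against mask tiles with pixel-wise binary cross-entropy (every pixel
weighted equally) under Adam. Stage 2 freezes LPNet, rebuilds one merged
probability map per training image, resizes it bilinearly to GMRNet's input
size — deliberately **without** thresholding, so the refinement network
sees the calibrated probabilities — and trains GMRNet against the
ground-truth mask resized with nearest-neighbour (which keeps it binary).
Stage 2 consumes exactly stage-1 outputs; ground truth never appears on
GMRNet's input side. A third, end-to-end fine-tuning stage is described in
the reference account but with no mechanism for back-propagating through
the merge-and-resize boundary; we do not implement it, and the two-stage
results below do not appear to need it.

The data split is **by plant** (all three views travel together), taking
`floor(0.85 n)` plants for training, so no view of a held-out plant leaks
into training.

The reference regime is 200 epochs, batch 32, learning rate 5e-4 on GPU
hardware. The package's CPU-scale preset uses 20 epochs (batch 16) for
LPNet and 30 epochs (batch 4) for GMRNet at learning rate 3e-3: the
refinement stage sees only a few dozen merged maps, so a small batch gives
it enough optimiser steps, and the shorter schedule needs the faster rate.
Both stages' losses are required (and tested) to fall by well over half.

## Counting

`analyse_particles()` labels maximal connected foreground regions — the
flood-fill object model of classical particle-analysis tools — under 4- or
8-connectivity (default 8, the common default of such tools; the reference
account does not state it). It is implemented as connected components of
the vectorised pixel-adjacency graph and is tested for exact partition
equality against an independent queue-based flood fill on hundreds of
random masks. Touching spikes necessarily merge into one object; this
undercount failure mode is inherent to the approach and deliberately
preserved (no watershed splitting). `min_area` (default 0) can drop
single-pixel specks; the scaled pipeline uses `min_area = 2` on its 64×64
refined masks. The per-plant count is the maximum over the three views.

## Metrics

With pixel counts TP, TN, FP, FN: precision, recall, accuracy and F1 take
their usual forms; JI = TP/(TP+FP+FN); E1 = (FP+FN)/total is the overall
misclassification rate, so `implied_error_pixels()` = round(E1 · total)
recovers "wrongly classified pixels per image"; E2 = (FPR + FNR)/2 is the
class-balanced type-I/II error. When a denominator is empty, a ratio is 1
if both sides are empty (perfect agreement on an empty class) and 0
otherwise. Dataset-level numbers are the **mean of per-image metrics**,
not pooled confusions, matching per-plant averaging over three views.
Object-level counting metrics fix TN = 0 (background is not an object), so
counting accuracy reduces to TP/(TP+FP+FN) — the Jaccard index of counts.

## The synthetic scene generator

No public dataset accompanies the method, so the package generates its own
study material: a uniform grey background, a green stem with leaf strokes,
and textured golden elliptical blobs as spikes, with the ground-truth mask
marking exactly the spike pixels. The generator emulates the features the
method actually exploits — single plant, uniform background, spikes
chromatically and texturally distinct from foliage, three views with
partial per-view visibility and a known total count — and nothing more. It
does **not** emulate awns or spikelet substructure, self-occlusion by
leaves, specular lighting, or field backgrounds; a pass on synthetic scenes
therefore demonstrates that the pipeline's machinery works end-to-end, not
that the reported real-data accuracies transfer.

Choices a scientist must fix, and our defaults: reference canvas
1656 × 1356 (the crop size of the cabinet images) with spike semi-axes
40--80 px; CPU preset 96 × 96 with semi-axes 4.5--7 px, 3 leaves, additive
Gaussian intensity noise (sd 4), minimum spike clearance 8 px. The 96 × 96
canvas with 64-px patches every 32 px is the smallest geometry that still
exercises overlapping tiles, clamped offsets, merging and multi-view
counting while keeping a pure-R training run to minutes. In the three-view
generator each spike is visible per non-reference view with probability
0.85, and one randomly chosen reference view shows all spikes — this makes
"maximum over views = plant total" hold by construction, which is the
regime the counting protocol assumes.

Gamma correction uses out = 255 · (in/255)^(1/γ): γ < 1 darkens and γ > 1
brightens, matching the darker-to-brighter ordering of the illumination
protocol (levels 0.1--2.5). Because outputs are rounded to integer levels,
the darkening direction is lossy: a γ-then-1/γ round trip is only
quantisation-accurate (± 2 levels) when the expanding application comes
first, and at γ = 0.1 (inverse slope 10) not even then; the tests encode
exactly this.

## Numerical and degenerate-input conventions

* Probability maps are thresholded at 0.5 with ties going to foreground;
  thresholding happens only after GMRNet.
* `resize_map()` is a separable resize on pixel-center coordinates
  (anisotropic; aspect ratio intentionally not preserved), bilinear for
  continuous maps, nearest-neighbour for masks; resizing to the same size
  is exactly the identity.
* Masks on disk are PNG with 0 = spike and 255 = background; in memory
  1 = spike. Reading tolerates near-binary files via a luminance-128 cut,
  with a strict mode.
* Empty masks, zero-spike scenes, zero-epoch training and empty datasets
  are all defined behaviours (tested), not errors — except where a
  contract is genuinely violated (dimension mismatches, non-binary masks,
  `gamma <= 0`, a canvas too small for the requested spikes), which abort
  with the offending quantity named.

## Scaled study conditions

The end-to-end acceptance run uses 14 plants × 3 views (42 scenes) of
96 × 96, per-plant spike counts drawn from 4--8, reduced widths (4, 8, 16),
64-px patches with 32-px step, and the schedules above (~8 minutes on one
CPU). Pixel F1 is evaluated on the held-out 15% of plants against the
nearest-resized truth at 64 × 64; exact-count agreement via the three-view
maximum is evaluated over all plants, since the counting stage has no
trained parameters. The acceptance script reports these quantities for a
given seed; at seed 1 it prints mean F1 0.962 and 100% count agreement.

## Known limitations

* The engine is pure R: fine at the CPU preset's scale, not meant for the
  reference 256-px, 91,800-patch regime.
* GMRNet can only be as good as the merged map it refines; with very few
  training plants it slightly blurs an already excellent LPNet output
  (the merged-map F1 ceiling is higher than the refined-mask F1 on the
  tiny preset).
* Counting inherits the linked-object undercount for touching spikes and,
  after aggressive downscaling, can merge spikes closer than the resize
  resolution; the generator's clearance default avoids the latter by
  construction.
* Real wheat imagery differs from the synthetic scenes in texture and
  occlusion structure; transferring the trained toy models to real images
  is not expected to work — retrain at the reference scale instead.
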