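# spikeseg

Pixel-wise segmentation and counting of wheat **spikes** (ears) on
single-plant RGB images, for plant phenotyping pipelines that need per-plant
spike counts and spike pixel areas from imaging-cabinet photographs.

## The method

Spikes are small textured structures on a plant that is mostly leaf and
stem, so `spikeseg` segments in two stages:

1. **LPNet** — an encoder–decoder network applied to overlapping square
   tiles (256 px tiles every 100 px at reference scale). Three encoder
   blocks (two 3×3 convs + ReLU + batch norm, 2×2 max-pool; widths 16, 64,
   128) feed a bottleneck of **three stacked hourglasses** (symmetric
   pyramids of 1×1→3×3→1×1 residual modules with elementwise skip
   additions, one scale-up and one scale-down between them), then three
   mirrored decoder blocks (stride-2 transpose conv, skip concatenation,
   two 3×3 convs) and a sigmoid head.
2. The per-tile probability maps are **merged** (mean over overlaps) into a
   full-size map, resized to 256×256, and refined by **GMRNet** — the same
   architecture without the hourglasses — giving the final spike mask.

Counting is classical particle analysis: flood-fill connected components
(8-connectivity) on the refined mask, and the per-plant count is

&nbsp;&nbsp;&nbsp;&nbsp;count(plant) = max over views v ∈ {0°, 120°, 240°} of #objects(mask_v),

since no single side view shows every spike. Segmentation quality is
summarised by precision, recall, accuracy, F1, the Jaccard index
JI = TP/(TP+FP+FN), the misclassification rate E1 = (FP+FN)/N, and the
class-balanced error E2 = (FPR+FNR)/2; counting quality by the same
formulas with TN ≡ 0.

Both networks are trained with Adam on pixel-wise binary cross-entropy,
in two modular stages (patch network first; the refinement network then
trains on the merged outputs of the frozen patch network). There is no
external deep-learning dependency: the package contains its own small
reverse-mode autodiff engine (channels-first arrays, convolutions as
shifted BLAS matmuls), verified by finite-difference gradient checks.

Because no public dataset accompanies the method, the package ships a
seeded synthetic scene generator (golden elliptical spikes, green foliage,
uniform background, three views with partial visibility and known counts)
so the entire pipeline — tiling, training, merging, refinement, counting,
evaluation, illumination robustness via gamma correction — runs end-to-end
from nothing.

## Worked example

```r
library(spikeseg)

plan_grid(1656, 1356, 256, 100)
#> <patch_grid> 1656x1356 image, 256 px tiles every 100 px: 15 x 12 = 180 tiles

s <- generate_scene(scene_config_cpu(n_spikes = 5), seed = 42)
s
#> <scene_sample> plant_1 @ 0 deg: 96x96, 5/5 spikes visible
analyse_particles(s$mask, connectivity = 8)
#> <particle_report> 5 object(s), connectivity 8, min_area 0

views <- generate_plant_views(scene_config_cpu(n_spikes = 7), seed = 3)
count_spikes_plant(lapply(views, function(v) v$mask))
#> <plant_count> views 7/6/7 -> final 7
```

The 180 tiles are the reference full-image tiling (15 row offsets × 12
column offsets); the particle report finds exactly the 5 generated spikes;
the three views of a 7-spike plant show 7, 6 and 7 spikes, and the
three-view maximum recovers the true count.

The full scaled experiment — generate 14 plants × 3 views, train both
stages, evaluate held-out segmentation and per-plant counts — is one call:

```r
ex <- run_spike_experiment(seed = 1)
ex
#> <spike_experiment> 14 plants (3 held out): mean pixel F1 0.962, exact-count agreement 100%
```

(about 6–8 minutes on one CPU). `tidy(ex)` returns the per-image held-out
metrics, `glance(ex)` the summary row, `autoplot(ex)` the predicted-vs-true
count plot; `illumination_sweep()` re-evaluates the trained models under
gamma-corrected (darker/brighter) versions of the scenes.

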