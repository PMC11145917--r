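---
title: "Methods: whole-brain c-Fos activity mapping with fosmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain c-Fos activity mapping with fosmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Immediate-early-gene (c-Fos) immunostaining marks recently active neurons.
High-speed volumetric light-sheet imaging of cleared mouse brain produces
dual-channel 3D stacks — a signal channel carrying the c-Fos
immunofluorescence and an autofluorescence channel carrying broadband tissue
fluorescence — at anisotropic voxel sizes around 1 x 1 x 3.5 µm. Turning
such stacks into per-region activated-cell counts requires (i) voxel-wise
segmentation of soma-scale bright spots, (ii) rejection of non-neuronal
bright structures (chiefly autofluorescent blood vessels), (iii) mapping of
cell centroids into a hierarchical reference atlas, and (iv) group-level
statistics over cohorts of animals. `fosmapr` implements this pipeline at
desk scale, with a synthetic phantom generator providing exact ground truth
so that every stage is testable without any external data.

# The segmentation network

The segmenter is a hybrid 3D shifted-window (Swin) transformer with a
U-shaped encoder–decoder:

* **Dilated convolution front end.** Three parallel 3D convolutions
  (kernel 3³, dilation rates 1/2/3, `conv_channels = 4` each) are
  concatenated and fused by a 1³ convolution to `fused_channels = 8`
  feature channels at full voxel resolution. This injects multi-scale local
  context (a convolutional prior) before tokenization. Setting
  `hybrid = FALSE` removes the block entirely and embeds raw voxels — the
  ablated pure-Swin variant used for the non-inferiority comparison.
* **Patch partition and linear embedding.** Non-overlapping
  `token_patch = 2x2x2` voxel groups become tokens, linearly embedded to
  width `C = embed_dim` and layer-normalized.
* **Encoder.** Four stages of Swin blocks with depths `(2, 2, 6, 2)`;
  patch merging (2³ token groups, linear reduction) between stages doubles
  the width: C, 2C, 4C, 8C. The deepest stage operates at 1/16 of the input
  resolution per axis and acts as the bottleneck.
* **Swin block.** Pre-norm windowed multi-head self-attention with learned
  relative-position bias, followed by a pre-norm MLP (GELU,
  `mlp_ratio = 4`), each with a residual connection. Blocks alternate
  between regular and cyclically shifted windows (shift = window/2); after
  a shift, an additive mask forbids attention between tokens whose original
  positions were not contiguous (the standard treatment of wrapped
  windows). The window (default 4³ tokens) is clamped per stage to the
  token grid; shifting is disabled when one window covers the whole grid.
* **Decoder.** Three patch-expanding stages (linear 2D -> 8 x D/2,
  rearranged to a 2x-finer grid) mirror the encoder; each is fused with the
  matching encoder skip by channel concatenation + linear reduction —
  exactly three skip connections. A final expansion restores voxel
  resolution; a linear head plus softmax yields two-class voxel
  probabilities.

Head counts default to `stage_width / 16` (minimum 1), giving a constant
head dimension of 16. Weights are initialized from N(0, 0.02²); LayerNorm
uses eps 1e-5.

## Training

The loss is class-weighted voxel cross-entropy plus per-patch soft Dice
(equal weights). Spot masks are extremely sparse (well under 1% positive
voxels), and an unweighted cross-entropy drives the network into the
all-background local optimum before the Dice term can act; the foreground
weight is therefore the batch background/foreground ratio, capped at 50.
Patches with empty masks contribute cross-entropy only (their Dice is
undefined). The optimizer is AdamW (default `lr = 1e-4`, decoupled weight
decay 0.01 on weight matrices only); every image patch is min–max
normalized to [0, 1]. The train/validation split is by patch id under the
training seed; validation Dice is the micro-averaged voxel Dice of the
argmax segmentation, and the best-epoch weights are restored at the end.

Numerically the package keeps two equivalent implementations of the same
graph: a double-precision R implementation (the reference, verified against
central finite differences) and a single-precision C++ core that fuses the
forward and backward pass of a batch; the test suite checks the two agree
to float tolerance. Training and inference use the fast core; the reference
path also serves dropout > 0.

## The scaled-down benchmark

The package's training benchmark uses a tiny configuration — C = 16,
window 4³, depths (2, 2, 6, 2) — on 200 synthetic 32³ patches drawn from
eight phantoms (60 cells each, no vessels, Gaussian noise SD 5), trained
for 20 epochs with batch size 8 and lr 1e-3 (the higher rate suits the
short schedule of the small benchmark; the conservative 1e-4 remains the
config default). The held-out Dice (20% of patches) is expected above 0.7,
and the hybrid variant is checked to be non-inferior (within 0.05) to the
ablated variant under identical seeds. These problem sizes keep the full
benchmark to a few minutes per variant on one CPU core.

# Training-mask generation

Spot-like training masks are generated statistically rather than by manual
annotation: the intensity threshold is `mean + k * SD` (population SD,
default `k = 3`, a classical z-cut) pooled over representative region boxes
(default: the whole volume); 26-neighbourhood local maxima above the
threshold are greedily suppressed so no two peaks are closer than
`min_separation_um = 8` (descending intensity, lexicographic (z, y, x)
tie-break — fully deterministic); accepted peaks are rendered as ellipsoids
of physical radius `spot_radius_um = 3` (soma-nucleus scale), converted
per axis by the voxel size. Fixed-radius ellipsoids rather than thresholded
component shapes are a deliberate simplification; the alternative would
follow the same interface.

# Post-processing filters

Whole volumes are segmented patch-wise (reflected halos, halo-cropped
stitching — voxel-identical to whole-volume inference for any voxel-wise
segmenter) in both channels with the same single-channel network. Three
filters then run in fixed order on 26-connected components of the
signal-channel mask:

1. **Autofluorescence filter**: components whose voxel-overlap fraction
   with the autofluorescence-channel mask is >= `af_overlap_frac = 0.5`
   are deleted — broadband structures (vessels, debris) appear in both
   channels, genuine c-Fos⁺ nuclei do not.
2. **Soma-size filter**: components outside
   `[soma_volume_um3_min, soma_volume_um3_max] = [50, 5000]` µm³ are
   deleted (closed bounds). The bounds bracket somata of roughly 5–20 µm
   diameter; sub-somatic specks are noise, oversized components are vessel
   fragments or clumps.
3. **Intensity filter**: background statistics are estimated robustly
   (median m and 1.4826·MAD) over voxels *outside* the mask; components
   with mean raw intensity below `m + k·σ̂` (`intensity_k = 3`) are
   deleted. The median/MAD estimator resists contamination by residual
   bright voxels, which a mean/SD estimator would not.

Each filter is idempotent, never adds voxels, and the removal accounting
(before − removed = after, removal sets disjoint) is exact by construction.
Cells are then extracted as 26-connected components with intensity-weighted
centroids, ordered by (z, y, x) for determinism.

# Atlas quantification

Registration is an input, not a computation: an affine 4x4 transform maps
image micrometre coordinates to atlas voxel coordinates (for the synthetic
workflow the atlas shares the image grid and the transform is a pure
scaling). Labels are looked up at the nearest voxel without interpolation;
cells landing outside the annotation get region 0 and are excluded from
counts (reported as unassigned). Hemispheres split at the midline index on
the mediolateral axis, ties assigned to the right. Counts aggregate to any
ontology level through parent links; densities divide by annotated region
volume; the volume ratio is the mask-positive fraction of a region's
voxels. Anterior–posterior profiles split a region's annotated AP extent
into equal half-open bins (last bin closed). All of these satisfy exact
conservation identities (level sums, hemisphere sums, layer sums, AP-bin
sums), which the test suite asserts.

Coordinates follow one convention everywhere: 0-based voxel indices ordered
(z, y, x); physical micrometres are index x voxel size; tables carry both.

# Group statistics

Per-region two-group comparisons use the pooled-variance Student's t
(Welch by flag), Benjamini–Hochberg q-values across regions, and a signed
fold change `r = (mean_a + eps)/(mean_b + eps)` reported as −1/r below 1
(pseudo-count `eps = 0.5` guards empty regions). The volcano
classification is `up` for fc > 1.4 and q < 0.05, `down` for fc < −1.4 and
q < 0.05, `ns` otherwise — both cuts strict. Relative z-scores standardize
each region over all animals pooled by default (placing all groups on one
scale; a control-only baseline is a config switch). The coefficient of
variation is the sample SD over the mean. Correlation structure uses
Spearman's rho (tie-averaged ranks, t-approximation p-values with n − 2
degrees of freedom), with each region's best partner chosen by maximum
absolute correlation (ties to the lower region index).

# The phantom generator

`generate_phantom()` emulates the statistical structure of dual-channel
stacks: a constant tissue background (default 100 a.u.); cells as
isotropic-in-µm Gaussian spots (sigma = radius/2, truncated at 2.5 sigma)
with radii 2–4 µm and peaks 300–600 a.u. in the *signal channel only*;
vessels as smoothed random-walk tubes (radius 3 µm) rendered into *both*
channels, with `autofl_bleed_frac = 0.6` of the vessel intensity appearing
in the signal channel; Gaussian noise added last. Placement enforces
margins from the volume border, between cells, and from vessels, so the
ground truth is exact: every planted cell produces exactly one local
maximum and no spot is clipped. The noise-free recovery study uses 200
cells (radius 3–4.5 µm, peaks 400–800) and 10 vessels in a 64 x 160 x 160
volume; these radii keep every thresholded cell component above the 50 µm³
soma bound on the anisotropic grid.

What the phantom does **not** emulate: the microscope point-spread
function, stitching seams, intensity inhomogeneity and bleaching,
heterogeneous staining backgrounds, touching cells. Passing the recovery
tests therefore demonstrates the correctness of the pipeline's mechanics
(segmentation, filtering, accounting, mapping) — not segmentation accuracy
on real tissue, which depends on training data the phantom cannot stand in
for.

The synthetic cohort tables draw per-animal counts as
`round(lognormal(log(mu_r * f_gr), sigma))`: lognormal dispersion matches
the heavy right tail of real per-region counts and makes parameter
recovery analytic. The parameter-recovery study plants a factor-2 effect
in 20 of 100 regions at sigma = 0.25 with n = 6 per group over 20 seeds
and measures the sensitivity and false-discovery rate of the volcano
classification at (1.4, 0.05). A factor-2 effect is deliberately the most
conservative member of the "at least two-fold" family: at these settings
the pooled t statistic has noncentrality around 4.4 at 10 degrees of
freedom, and the Benjamini–Hochberg step-up over 100 regions with ~20 true
effects implies an effective per-test alpha near 0.01, so per-region power
sits near 0.86–0.88. The measured sensitivity lands there too (the FDR
stays a comfortable order of magnitude under 0.1); sensitivities above 0.9
require planted factors of roughly 2.3 or more. The study conditions are
kept at the conservative factor rather than tuned upward.

# Tiling defaults and numerical choices

* Tile core 48³ with halo 8 (model input 64³). 64 is divisible by
  token_patch x 2³ = 16 and keeps every stage's token grid divisible by
  the 4³ window; the tempting 64³-core/halo-8 alternative (input 80³)
  fails window divisibility at stage 3 and was rejected. Oversized cores
  on thin volumes fall back to a single reflect-padded tile per axis.
* Border handling is mirror reflection (no duplicated edge sample) — no
  artificial intensity edges enter the convolutions or attention windows.
* Empty-vs-empty segmentation metrics are defined as 1.0 and flagged.
* All randomness flows through explicit seeds (phantoms, atlas, cohort
  draws, weight init, the training split/shuffle); every stage is
  reproducible bit-for-bit on a single thread.

# Limitations

* Deformable registration to a real atlas is out of scope; the affine (or
  precomputed coordinates) is trusted as given.
* Touching cells are not split (no watershed/instance segmentation);
  counts are connected components.
* The scaled-down network is far smaller than what whole-brain inference
  would use, and its accuracy numbers are properties of the synthetic
  benchmark, not of real tissue.
* Terabyte-scale streaming and GPU execution are non-goals.
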