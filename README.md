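# fosmapr

Whole-brain c-Fos activity mapping in R: dual-channel 3D segmentation of
activity-labeled (c-Fos⁺) neurons with a hybrid shifted-window transformer,
false-positive filtering against the autofluorescence channel, hierarchical
atlas quantification, and cohort-level statistics — exercised end to end on
synthetic phantoms with exact ground truth.

## Who this is for

Neuroscientists and imaging methodologists who quantify activated neurons in
volumetric light-sheet stacks of cleared mouse brain (voxel size on the order
of 1 × 1 × 3.5 µm, a signal channel carrying c-Fos immunofluorescence and an
autofluorescence channel carrying broadband tissue fluorescence), and who need
every stage of such a pipeline — training-mask generation, network training,
tiled inference, filtering, atlas counts, group statistics — as tested,
scriptable R functions.

## What is inside

* **Segmentation network.** A U-shaped 3D Swin transformer: a dilated
  convolution front end (rates 1/2/3) feeding a patch-partition + linear
  embedding, a four-stage encoder with block depths (2, 2, 6, 2) and widths
  C, 2C, 4C, 8C (patch merging between stages; the deepest stage is the
  bottleneck), and a decoder with three patch-expanding stages fused with the
  three encoder skips, ending in a linear softmax head. Shifted windows use
  the standard cyclic shift with masking of wrapped token pairs and learned
  relative-position bias. Training (class-weighted cross-entropy + soft Dice,
  AdamW) runs in a single-precision C++ core with a double-precision R
  reference implementation verified by finite differences.
* **Post-processing.** Halo-cropped tiled inference on both channels, then
  three component filters in fixed order: autofluorescence overlap
  (fraction ≥ 0.5 removed), soma volume ([50, 5000] µm³ kept), and robust
  intensity (components below median + 3·1.4826·MAD of the background
  removed); then per-cell extraction with intensity-weighted centroids.
* **Atlas quantification.** Affine mapping of centroids into a labeled
  annotation volume with a hierarchical ontology; counts/densities at any
  level, layer metrics with volume ratios, hemisphere splits,
  anterior–posterior profiles — all with exact conservation identities.
* **Group statistics.** Pooled Student's t with Benjamini–Hochberg FDR,
  signed fold change with the volcano classification (|fc| > 1.4,
  q < 0.05), relative z-scores, coefficients of variation, and Spearman
  correlation structure with best-partner maps.
* **Synthetic data.** Phantom volumes (Gaussian soma-scale spots in the
  signal channel, random-walk vessel tubes in both channels, configurable
  noise) with exact ground truth, toy hierarchical atlases, and lognormal
  cohort count tables with planted effects.

## Worked example

Simulate a noise-free dual-channel phantom with 200 cells and 10
autofluorescent vessels, segment both channels, and run the filter chain:

```r
library(fosmapr)
spec <- phantom_spec(shape = c(64L, 160L, 160L), n_cells = 200L, n_vessels = 10L,
                     cell_radius_um = c(3, 4.5), cell_peak_intensity = c(400, 800),
                     noise_sd = 0, seed = 2024)
sample <- generate_phantom(spec)
seg  <- threshold_segmenter(150)   # deterministic stand-in segmenter for the demo
cfos <- mask_volume(seg(sample$signal$data), spec$voxel_size)
af   <- mask_volume(seg(sample$autofl$data), spec$voxel_size)
res  <- apply_filter_chain(cfos, af, sample$signal, default_config())
res$report
#> <filter_report> 210 components -> 200 (removed: 10 autofluorescence, 0 no-soma, 0 intensity)
cells <- extract_cells(res$mask, sample$signal)
nrow(cells)
#> [1] 200
```

The 210 segmented components are the 200 planted cells plus the 10 vessels;
the autofluorescence filter removes exactly the vessels (they are bright in
both channels) and every planted cell survives. Group comparison on a
synthetic cohort with effects planted in regions R01 and R02:

```r
des <- group_design(groups = c("ctrl", "stress"), n_per_group = 6L,
                    regions = sprintf("R%02d", 1:12), baseline_mean = 100,
                    effects = list(stress = c(R01 = 2.5, R02 = 2)),
                    sigma = 0.25, seed = 42)
tab <- region_group_stats(generate_group_counts(des), "stress", "ctrl")
head(tab[, c("region", "mean_a", "mean_b", "t", "q", "fold_change",
             "significance_class")], 4)
#>   region mean_a mean_b     t       q fold_change significance_class
#> 1    R01  224.8  106.0  4.75 0.00939        2.12                 up
#> 2    R02  189.8   95.7  4.21 0.01072        1.98                 up
#> 3    R12   94.2  120.8 -1.63 0.53457       -1.28                 ns
#> 4    R06  113.0   96.5  1.13 0.55083        1.17                 ns
```

Both planted regions are recovered as `up` (fold change ≈ 2, q < 0.05); the
unperturbed regions stay `ns`. To train the network on synthetic patches, see
`?build_training_set`, `?build_model` and `?train_model`, or run the full
seven-stage pipeline with `run_pipeline(default_config(), "workspace")`.

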