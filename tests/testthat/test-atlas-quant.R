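make_mapped <- function(atlas, per_leaf = 3L, seed = 2) {
  cells <- planted_cells(atlas, per_leaf = per_leaf, seed = seed)
  map_cells_to_atlas(cells, make_affine(scale = 1 / atlas$voxel_size), atlas)
}

test_that("identity-scaled mapping reads annotation labels and hemispheres", {
  at <- generate_toy_atlas(shape = c(16L, 32L, 32L))
  cells <- planted_cells(at, per_leaf = 2L)
  mapped <- map_cells_to_atlas(cells, make_affine(scale = 1 / at$voxel_size), at)
  for (i in seq_len(nrow(mapped))) {
    expect_identical(mapped$region_id[i],
                     at$annotation[mapped$atlas_z[i] + 1L,
                                   mapped$atlas_y[i] + 1L,
                                   mapped$atlas_x[i] + 1L])
    expect_identical(mapped$hemisphere[i],
                     if (mapped$atlas_x[i] < at$midline_index) "L" else "R")
  }
  # a cell outside the brain box gets region 0 / unassigned
  out <- data.frame(cell_id = 1L, z_um = 0, y_um = 0, x_um = 0,
                    region_id = 0L, hemisphere = "unassigned")
  m2 <- map_cells_to_atlas(out, make_affine(scale = 1 / at$voxel_size), at)
  expect_identical(m2$region_id, 0L)
  expect_identical(m2$hemisphere, "unassigned")
  expect_error(map_cells_to_atlas(cells, make_affine(scale = c(0, 1, 1)), at),
               "singular")
})

test_that("a pure one-voxel translation shifts labels like a brute-force lookup", {
  at <- generate_toy_atlas(shape = c(16L, 32L, 32L))
  cells <- planted_cells(at, per_leaf = 2L, seed = 5)
  T1 <- make_affine(scale = 1 / at$voxel_size, translation = c(1, 0, 0))
  mapped <- map_cells_to_atlas(cells, T1, at)
  for (i in seq_len(nrow(mapped))) {
    vz <- round(cells$z_um[i] / at$voxel_size[1]) + 1L
    want <- if (vz + 1L <= dim(at$annotation)[1])
      at$annotation[vz + 1L,
                    round(cells$y_um[i] / at$voxel_size[2]) + 1L,
                    round(cells$x_um[i] / at$voxel_size[3]) + 1L] else 0L
    expect_identical(mapped$region_id[i], want)
  }
})

test_that("counts are conserved across ontology levels (partition identity)", {
  at <- generate_toy_atlas(shape = c(24L, 32L, 32L), n_superregions = 3L,
                           n_children_per = 2L)
  mapped <- make_mapped(at, per_leaf = 3L)
  n_total <- nrow(mapped)
  for (lev in 1:3) {
    tab <- counts_by_level(mapped, at, lev)
    expect_equal(sum(tab$count) + attr(tab, "unassigned"), n_total)
  }
  # 3 cells per leaf -> each level-2 parent holds 3 * n_children
  t2 <- counts_by_level(mapped, at, 2)
  expect_true(all(t2$count == 3L * 2L))
  # zero cells: full region index, all-zero counts
  empty <- mapped[0, ]
  t0 <- counts_by_level(empty, at, 3)
  expect_identical(nrow(t0), 6L)
  expect_true(all(t0$count == 0L))
  expect_true(all(t0$region_volume_mm3 > 0))
  expect_error(counts_by_level(mapped, at, 9), "level not present")
})

test_that("volume ratios report the mask fraction per region", {
  at <- generate_toy_atlas(shape = c(16L, 32L, 32L))
  leaf <- at$ontology$id[at$ontology$level == 3][1]
  sel <- which(at$annotation == leaf)
  m <- array(0, dim(at$annotation))
  m[sel[seq_len(length(sel) %/% 2)]] <- 1     # exactly half the leaf voxels
  mapped <- make_mapped(at)
  tab <- counts_by_level(mapped, at, 3, mask = m)
  expect_equal(tab$volume_ratio[tab$region_id == leaf][1],
               (length(sel) %/% 2) / length(sel))
  t_empty <- counts_by_level(mapped, at, 3, mask = m * 0)
  expect_true(all(t_empty$volume_ratio == 0))
})

test_that("layer metrics conserve the parent count and measure occupancy", {
  at <- generate_toy_atlas(shape = c(24L, 32L, 32L), with_layers = TRUE,
                           n_layers = 3L)
  mapped <- make_mapped(at, per_leaf = 2L)
  parent <- at$ontology$id[at$ontology$level == 3][1]
  lm <- layer_metrics(mapped, NULL, at, parent)
  expect_identical(nrow(lm), 3L)
  kids <- at$ontology$id[!is.na(at$ontology$parent_id) &
                           at$ontology$parent_id == parent]
  expect_equal(sum(lm$count), sum(mapped$region_id %in% kids))
  expect_true(all(lm$volume_ratio == 0))
  # half-filled layer mask
  l1 <- lm$region_id[1]
  sel <- which(at$annotation == l1)
  m <- array(0, dim(at$annotation)); m[sel[seq_len(length(sel) %/% 2)]] <- 1
  lm2 <- layer_metrics(mapped, m, at, parent)
  expect_equal(lm2$volume_ratio[1], (length(sel) %/% 2) / length(sel))
  expect_error(layer_metrics(mapped, NULL, at, 1L), "no layer-tagged children")
})

test_that("hemisphere counts add up to the bilateral counts", {
  at <- generate_toy_atlas(shape = c(16L, 32L, 32L))
  mapped <- make_mapped(at, per_leaf = 5L, seed = 7)
  hc <- hemisphere_counts(mapped, at, 3)
  t3 <- counts_by_level(mapped, at, 3)
  expect_equal(hc$count_L + hc$count_R, hc$count_total)
  expect_equal(hc$count_total, t3$count[match(hc$region_id, t3$region_id)])
  # all cells on one side: the other column is zero
  left <- mapped[mapped$hemisphere == "L", ]
  hcl <- hemisphere_counts(left, at, 3)
  expect_true(all(hcl$count_R == 0L))
})

test_that("anterior-posterior bins partition the region count", {
  at <- generate_toy_atlas(shape = c(24L, 32L, 32L))
  mapped <- make_mapped(at, per_leaf = 8L, seed = 9)
  region <- at$ontology$id[at$ontology$level == 2][1]
  ap <- ap_profile(mapped, at, region, n_bins = 4)
  leaves <- at$ontology$id[!is.na(at$ontology$parent_id) &
                             at$ontology$parent_id == region]
  expect_equal(sum(ap$count), sum(mapped$region_id %in% leaves))
  expect_identical(nrow(ap), 4L)
  # degenerate: all region cells forced to the anterior tip land in bin 1
  tip <- mapped[mapped$region_id %in% leaves, ]
  zmin <- min(which(apply(array(at$annotation %in% leaves,
                                dim(at$annotation)), 1, any))) - 1L
  tip$atlas_z <- zmin
  ap2 <- ap_profile(tip, at, region, n_bins = 3)
  expect_equal(sum(ap2$count[ap2$bin == 1]), nrow(tip))
  expect_equal(sum(ap2$count[ap2$bin > 1]), 0L)
  expect_error(ap_profile(mapped, at, 99999L, 3), "zero annotated voxels")
})
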