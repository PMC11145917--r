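# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

tiny_volume <- function(dims = c(8L, 16L, 16L), seed = 1, max_val = 1000) {
  set.seed(seed)
  intensity_volume(array(sample.int(max_val, prod(dims), replace = TRUE),
                         dims))
}

random_mask <- function(dims, p = 0.3, seed = 1) {
  set.seed(seed)
  mask_volume(array(rbinom(prod(dims), 1, p), dims))
}

# brute-force reflection padding: grows the array one layer at a time by
# mirroring about the current outermost retained sample
brute_reflect_pad <- function(x, pad) {
  ref1 <- function(i, n) {
    while (i < 0 || i >= n) {
      if (i < 0) i <- -i
      if (i >= n) i <- 2 * (n - 1) - i
    }
    i
  }
  d <- dim(x)
  out <- array(NA_real_, d + 2 * pad)
  for (z in seq_len(d[1] + 2 * pad)) for (y in seq_len(d[2] + 2 * pad))
    for (x3 in seq_len(d[3] + 2 * pad))
      out[z, y, x3] <- x[ref1(z - 1 - pad, d[1]) + 1,
                         ref1(y - 1 - pad, d[2]) + 1,
                         ref1(x3 - 1 - pad, d[3]) + 1]
  out
}

# exhaustive voxel-wise confusion counts
brute_confusion <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else if (gt[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# brute-force Benjamini-Hochberg step-up adjusted p-values
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# small phantom with noise-free spots for detection tests
clean_phantom <- function(n_cells = 50L, seed = 11) {
  generate_phantom(phantom_spec(shape = c(48L, 96L, 96L), n_cells = n_cells,
                                n_vessels = 0L, noise_sd = 0, seed = seed))
}

tiny_model_cfg <- function(...) {
  hswin3d_config(embed_dim = 8L, window = c(2L, 2L, 2L),
                 depths = c(1L, 1L, 1L, 1L), heads = c(1L, 2L, 2L, 4L),
                 conv_channels = 2L, fused_channels = 3L, mlp_ratio = 2,
                 seed = 5L, ...)
}

# deterministic toy cell table in atlas voxel space (identity mapping)
planted_cells <- function(atlas, per_leaf = 3L, seed = 2) {
  set.seed(seed)
  leaves <- sort(setdiff(unique(as.vector(atlas$annotation)), 0L))
  rows <- list()
  for (lf in leaves) {
    vox <- which(atlas$annotation == lf)
    pick <- sample(vox, per_leaf)
    co <- arrayInd(pick, dim(atlas$annotation)) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      z_um = co[, 1] * atlas$voxel_size[1],
      y_um = co[, 2] * atlas$voxel_size[2],
      x_um = co[, 3] * atlas$voxel_size[3])
  }
  cells <- do.call(rbind, rows)
  cells$cell_id <- seq_len(nrow(cells))
  cells$region_id <- 0L
  cells$hemisphere <- "unassigned"
  cells
}
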