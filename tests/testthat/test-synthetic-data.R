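test_that("an empty phantom is constant background in both channels", {
  s <- generate_phantom(phantom_spec(shape = c(16L, 24L, 24L), n_cells = 0L,
                                     n_vessels = 0L, noise_sd = 0, seed = 1))
  expect_true(all(s$signal$data == 100))
  expect_true(all(s$autofl$data == 100))
  expect_identical(nrow(s$truth_cells), 0L)
})

test_that("a noise-free phantom has exactly one local maximum per planted cell", {
  s <- clean_phantom(n_cells = 50L)
  x <- s$signal$data
  d <- dim(x)
  above <- x > 100
  # exhaustive 26-neighbourhood local-maximum scan
  n_max <- 0L
  maxima <- NULL
  for (i in which(above)) {
    co <- arrayInd(i, d)
    zz <- max(1, co[1] - 1):min(d[1], co[1] + 1)
    yy <- max(1, co[2] - 1):min(d[2], co[2] + 1)
    xx <- max(1, co[3] - 1):min(d[3], co[3] + 1)
    if (x[i] >= max(x[zz, yy, xx])) {
      n_max <- n_max + 1L
      maxima <- rbind(maxima, co - 1L)
    }
  }
  expect_identical(n_max, 50L)
  # every maximum lies within one voxel of a truth centroid
  truth <- as.matrix(s$truth_cells[, c("z_vox", "y_vox", "x_vox")])
  for (r in seq_len(nrow(maxima))) {
    dmin <- min(apply(abs(sweep(truth, 2, maxima[r, ])), 1, max))
    expect_lt(dmin, 1)
  }
})

test_that("phantoms are deterministic functions of their spec", {
  sp <- phantom_spec(shape = c(16L, 32L, 32L), n_cells = 10L, n_vessels = 2L,
                     noise_sd = 4, seed = 9)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$signal$data, b$signal$data)
  expect_identical(a$autofl$data, b$autofl$data)
  expect_identical(a$truth_cells, b$truth_cells)
})

test_that("vessels appear in both channels, cells in the signal channel only", {
  s <- generate_phantom(phantom_spec(shape = c(24L, 64L, 64L), n_cells = 8L,
                                     n_vessels = 3L, noise_sd = 0,
                                     autofl_bleed_frac = 0.6, seed = 4))
  v <- s$truth_vessel_mask$data == 1
  expect_gt(sum(v), 0)
  expect_true(all(s$autofl$data[v] == 100 + 300))
  expect_true(all(s$signal$data[v] >= 100 + 0.6 * 300))
  # autofluorescence channel contains nothing but vessels + background
  expect_true(all(s$autofl$data[!v] == 100))
})

test_that("the toy atlas ontology matches its annotation", {
  at <- generate_toy_atlas(shape = c(16L, 32L, 32L), n_superregions = 2L,
                           n_children_per = 2L)
  expect_identical(nrow(at$ontology), 1L + 2L + 4L)
  labels <- sort(setdiff(unique(as.vector(at$annotation)), 0L))
  leaves <- at$ontology$id[at$ontology$level == 3]
  expect_identical(labels, sort(leaves))
  # every annotated label reaches the root through parent links
  for (lb in labels) {
    cur <- lb
    depth <- 0L
    while (!is.na(cur) && depth < 10L) {
      row <- match(cur, at$ontology$id)
      expect_false(is.na(row))
      cur <- at$ontology$parent_id[row]
      depth <- depth + 1L
    }
    expect_lt(depth, 10L)
  }
  # levels increase from root to leaves
  for (i in seq_len(nrow(at$ontology))) {
    pid <- at$ontology$parent_id[i]
    if (!is.na(pid))
      expect_gt(at$ontology$level[i], at$ontology$level[match(pid, at$ontology$id)])
  }
})

test_that("layer slabs conserve their parent's annotated volume", {
  at <- generate_toy_atlas(shape = c(24L, 32L, 32L), n_superregions = 2L,
                           n_children_per = 2L, with_layers = TRUE,
                           n_layers = 3L)
  ont <- at$ontology
  for (leaf in ont$id[ont$level == 3]) {
    kids <- ont$id[!is.na(ont$parent_id) & ont$parent_id == leaf]
    expect_gte(length(kids), 2L)
    vol_kids <- sum(at$annotation %in% kids)
    # the leaf itself is not annotated when layered; its volume is its slabs'
    expect_gt(vol_kids, 0L)
  }
  # layered leaves partition the brain box exactly like the unlayered atlas
  at0 <- generate_toy_atlas(shape = c(24L, 32L, 32L), n_superregions = 2L,
                            n_children_per = 2L, with_layers = FALSE)
  expect_identical(sum(at$annotation > 0), sum(at0$annotation > 0))
})

test_that("atlas bundles survive a TIFF/JSON round trip", {
  at <- generate_toy_atlas(shape = c(16L, 32L, 32L), with_layers = TRUE)
  ann <- tempfile(fileext = ".tif"); ont <- tempfile(fileext = ".json")
  write_atlas(at, ann, ont)
  back <- read_atlas(ann, ont)
  expect_equal(back$annotation, at$annotation)
  expect_equal(back$ontology$id, at$ontology$id)
  expect_equal(back$ontology$layer, at$ontology$layer)
  expect_identical(back$midline_index, at$midline_index)
})

test_that("degenerate dispersion recovers the planted fold change exactly", {
  des <- group_design(groups = c("ctrl", "stress"), n_per_group = 3L,
                      regions = 1:4, baseline_mean = 100,
                      effects = list(stress = c("2" = 2)), sigma = 0, seed = 1)
  counts <- generate_group_counts(des)
  m <- tapply(counts$count, list(counts$group, counts$region), mean)
  expect_equal(unname(m["stress", "2"] / m["ctrl", "2"]), 2)
  expect_true(all(m["stress", c("1", "3", "4")] == m["ctrl", c("1", "3", "4")]))
  expect_identical(attr(counts, "effect_regions")$stress, "2")
})

test_that("group count tables are reproducible under a fixed seed", {
  des <- group_design(regions = 1:10, sigma = 0.25, seed = 33)
  expect_identical(generate_group_counts(des), generate_group_counts(des))
})
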