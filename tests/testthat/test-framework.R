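test_that("volume TIFF round trip is voxel-identical for 16-bit data", {
  vol <- tiny_volume(c(8L, 16L, 16L), max_val = 65535)
  path <- tempfile(fileext = ".tif")
  write_volume(vol, path)
  back <- read_volume(path, "signal", vol$voxel_size)
  expect_identical(dim(back$data), dim(vol$data))
  expect_equal(back$data, vol$data)
})

test_that("a directory of per-plane TIFFs reads as a z-stack in lexicographic order", {
  d <- tempfile(); dir.create(d)
  planes <- lapply(1:3, function(z) matrix(z * 10 + seq_len(16), 4, 4))
  for (z in 1:3)
    write_volume(intensity_volume(array(planes[[z]], c(1, 4, 4))),
                 file.path(d, sprintf("plane_%02d.tif", z)))
  vol <- read_volume(d)
  expect_identical(dim(vol$data), c(3L, 4L, 4L))
  for (z in 1:3) expect_equal(vol$data[z, , ], planes[[z]])
})

test_that("inconsistent plane shapes are rejected", {
  d <- tempfile(); dir.create(d)
  write_volume(intensity_volume(array(1, c(1, 4, 4))), file.path(d, "a.tif"))
  write_volume(intensity_volume(array(1, c(1, 5, 4))), file.path(d, "b.tif"))
  expect_error(read_volume(d), "inconsistent plane shapes")
  expect_error(read_volume(tempfile()), "not found")
})

test_that("volume constructors enforce their invariants", {
  expect_error(intensity_volume(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(intensity_volume(array(1, c(2, 2)))) # not 3D
  expect_error(intensity_volume(array(1, c(2, 2, 2)), voxel_size = c(0, 1, 1)))
  expect_error(mask_volume(array(2, c(2, 2, 2))), "0 or 1")
})

test_that("trivial tiling returns the volume unchanged", {
  vol <- tiny_volume(c(32L, 32L, 32L))
  tiles <- tile_volume(vol, c(32L, 32L, 32L), halo = 0L)
  expect_length(tiles, 1L)
  expect_equal(tiles[[1]]$data, vol$data)
  expect_error(tile_volume(vol, c(16L, 16L, 16L), halo = -1L), "halo")
})

test_that("core tiles partition the volume exactly", {
  vol <- tiny_volume(c(32L, 32L, 32L))
  tiles <- tile_volume(vol, c(16L, 16L, 16L), halo = 0L)
  expect_length(tiles, 8L)
  rec <- array(NA_real_, dim(vol$data))
  for (tl in tiles) {
    o <- tl$spec$core_origin
    rec[o[1] + 1:16, o[2] + 1:16, o[3] + 1:16] <- tl$data
  }
  expect_equal(rec, vol$data)
})

test_that("halo padding matches a brute-force reflection oracle", {
  vol <- tiny_volume(c(20L, 20L, 20L), seed = 3)
  halo <- 4L
  tiles <- tile_volume(vol, c(16L, 16L, 16L), halo = halo)
  expect_length(tiles, 8L)
  expect_true(all(vapply(tiles, function(t) all(dim(t$data) == 24L), logical(1))))
  # oracle: pad the whole volume (halo + clipped-core overhang) by brute force
  padded <- brute_reflect_pad(vol$data, 16L)
  for (tl in tiles) {
    o <- tl$spec$core_origin
    expect_equal(tl$data,
                 padded[16L - halo + o[1] + 1:24, 16L - halo + o[2] + 1:24,
                        16L - halo + o[3] + 1:24])
  }
})

test_that("tile then stitch is the identity (property over random geometries)", {
  set.seed(7)
  for (rep in 1:8) {
    dims <- sample(6:40, 3, replace = TRUE)
    core <- sample(4:20, 3, replace = TRUE)
    halo <- sample(0:5, 1)
    m <- random_mask(dims, seed = rep)
    tiles <- tile_volume(m, core, halo)
    back <- stitch_masks(tiles, dims, m$voxel_size)
    expect_equal(back$data, m$data,
                 info = sprintf("dims=%s core=%s halo=%d",
                                paste(dims, collapse = ","),
                                paste(core, collapse = ","), halo))
  }
})

test_that("gaps and double coverage in a tiling are detected", {
  m <- random_mask(c(16L, 16L, 16L))
  tiles <- tile_volume(m, c(8L, 8L, 8L), halo = 2L)
  expect_error(stitch_masks(tiles[-3], dim(m$data)), "incomplete tiling")
  expect_error(stitch_masks(c(tiles, tiles[2]), dim(m$data)), "overlapping")
})

test_that("an empty config document yields the documented defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines("", path)
  cfg <- load_config(path)
  expect_identical(cfg$model$depths, c(2L, 2L, 6L, 2L))
  expect_identical(cfg$tile$core_shape, c(48L, 48L, 48L))
  expect_equal(cfg$stats$fc_cut, 1.4)
  expect_equal(cfg$stats$q_cut, 0.05)
})

test_that("out-of-range and unknown config keys are rejected", {
  path <- tempfile(fileext = ".yaml")
  writeLines("tile:\n  halo: -1", path)
  expect_error(load_config(path), "out of range")
  writeLines("no_such_section:\n  a: 1", path)
  expect_error(load_config(path), "unknown config key")
  writeLines("filters:\n  no_such_param: 3", path)
  expect_error(load_config(path), "unknown config key")
})

test_that("config save/load round trip preserves every value", {
  cfg <- default_config()
  cfg$filters$af_overlap_frac <- 0.33
  cfg$model$embed_dim <- 16L
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    save_config(cfg, path)
    back <- load_config(path)
    expect_equal(unclass(back), unclass(validate_config(fosmapr:::normalize_config_types(cfg))),
                 tolerance = 1e-12)
  }
})
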