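vs1 <- c(1, 1, 1)

test_that("autofluorescence filter removes components by overlap fraction", {
  m <- array(0, c(6L, 6L, 6L))
  m[2:3, 2:3, 2:3] <- 1                       # 8-voxel component
  cfos <- mask_volume(m, vs1)
  af_all <- mask_volume(m, vs1)               # fully inside the af mask
  r <- autofluorescence_filter(cfos, af_all, overlap_frac = 0.5)
  expect_equal(sum(r$mask$data), 0)
  expect_identical(nrow(r$removed), 1L)
  # empty reference: identity
  r2 <- autofluorescence_filter(cfos, mask_volume(array(0, c(6L, 6L, 6L)), vs1), 0.5)
  expect_equal(r2$mask$data, cfos$data)
  expect_identical(nrow(r2$removed), 0L)
  # hand case: 3 of 8 voxels overlap -> fraction 0.375
  af3 <- array(0, c(6L, 6L, 6L))
  af3[2, 2, 2] <- af3[2, 2, 3] <- af3[2, 3, 2] <- 1
  kept <- autofluorescence_filter(cfos, mask_volume(af3, vs1), 0.5)
  expect_equal(kept$mask$data, cfos$data)
  gone <- autofluorescence_filter(cfos, mask_volume(af3, vs1), 0.3)
  expect_equal(sum(gone$mask$data), 0)
  expect_equal(gone$removed$overlap_fraction, 0.375)
  expect_error(autofluorescence_filter(cfos, random_mask(c(4L, 4L, 4L)), 0.5),
               "shape mismatch")
})

test_that("soma filter enforces closed physical-volume bounds", {
  vs <- c(3.5, 1, 1)                          # voxel volume 3.5 um^3
  m <- array(0, c(8L, 12L, 12L))
  m[2, 2, 2] <- 1                             # 1 voxel = 3.5 um^3, too small
  m[5, 4:9, 4:9] <- 1                         # 36 voxels = 126 um^3, kept
  r <- soma_filter(mask_volume(m, vs), vmin_um3 = 50, vmax_um3 = 5000)
  expect_equal(sum(r$mask$data), 36)
  expect_identical(r$removed$reason, "no_soma")
  # component exactly at vmin is kept (closed bound): 2 voxels at 25 um^3 each
  vs2 <- c(25, 1, 1)
  m2 <- array(0, c(4L, 4L, 4L)); m2[2, 2, 2:3] <- 1
  r2 <- soma_filter(mask_volume(m2, vs2), vmin_um3 = 50, vmax_um3 = 5000)
  expect_equal(sum(r2$mask$data), 2)
  # empty input stays empty
  r3 <- soma_filter(mask_volume(array(0, c(4L, 4L, 4L)), vs), 50, 5000)
  expect_equal(sum(r3$mask$data), 0)
})

test_that("intensity filter removes components at background level", {
  set.seed(8)
  raw <- array(100 + rnorm(16^3, 0, 3), c(16L, 16L, 16L))
  m <- array(0, c(16L, 16L, 16L))
  m[3:5, 3:5, 3:5] <- 1
  raw[3:5, 3:5, 3:5] <- 400                   # bright, genuine
  m[10:12, 10:12, 10:12] <- 1                 # dim ghost at background level
  r <- intensity_filter(mask_volume(m, vs1),
                        intensity_volume(pmax(raw, 0), vs1), k = 3)
  expect_identical(nrow(r$removed), 1L)
  expect_equal(sum(r$mask$data), 27)
  expect_true(all(r$mask$data[3:5, 3:5, 3:5] == 1))
  # k = 0: only components dimmer than the background median go
  r0 <- intensity_filter(mask_volume(m, vs1),
                         intensity_volume(pmax(raw, 0), vs1), k = 0)
  expect_identical(nrow(r0$removed), 1L)
  expect_error(intensity_filter(mask_volume(array(1, c(4L, 4L, 4L)), vs1),
                                intensity_volume(array(1, c(4L, 4L, 4L)), vs1), 3),
               "no background")
})

test_that("filters are idempotent and never add voxels", {
  s <- generate_phantom(phantom_spec(shape = c(32L, 64L, 64L), n_cells = 15L,
                                     n_vessels = 3L, noise_sd = 0,
                                     cell_radius_um = c(3, 4.5),
                                     cell_peak_intensity = c(400, 800),
                                     seed = 12))
  seg <- threshold_segmenter(150)
  cfos <- mask_volume(seg(s$signal$data), s$signal$voxel_size)
  af <- mask_volume(seg(s$autofl$data), s$signal$voxel_size)
  f1 <- autofluorescence_filter(cfos, af, 0.5)
  f1b <- autofluorescence_filter(f1$mask, af, 0.5)
  expect_equal(f1b$mask$data, f1$mask$data)
  expect_true(all(f1$mask$data <= cfos$data))
  f2 <- soma_filter(f1$mask, 50, 5000)
  f2b <- soma_filter(f2$mask, 50, 5000)
  expect_equal(f2b$mask$data, f2$mask$data)
  f3 <- intensity_filter(f2$mask, s$signal, 3)
  f3b <- intensity_filter(f3$mask, s$signal, 3)
  expect_equal(f3b$mask$data, f3$mask$data)
  expect_true(all(f3$mask$data <= cfos$data))
})

test_that("the filter-report accounting identity holds exactly", {
  s <- generate_phantom(phantom_spec(shape = c(32L, 64L, 64L), n_cells = 12L,
                                     n_vessels = 2L, noise_sd = 0,
                                     cell_radius_um = c(3, 4.5),
                                     cell_peak_intensity = c(400, 800),
                                     seed = 13))
  seg <- threshold_segmenter(150)
  res <- apply_filter_chain(mask_volume(seg(s$signal$data), s$signal$voxel_size),
                            mask_volume(seg(s$autofl$data), s$signal$voxel_size),
                            s$signal, default_config())
  rp <- res$report
  expect_equal(rp$components_before - rp$removed_autofluorescence -
                 rp$removed_no_soma - rp$removed_intensity,
               rp$components_after)
})

test_that("intensity-weighted centroids match hand computation", {
  m <- array(0, c(4L, 4L, 4L)); m[1:2, 1, 1] <- 1
  raw <- array(10, c(4L, 4L, 4L))
  cells <- extract_cells(mask_volume(m, c(3.5, 1, 1)),
                         intensity_volume(raw, c(3.5, 1, 1)))
  expect_identical(nrow(cells), 1L)
  expect_equal(cells$z_vox, 0.5)
  expect_equal(cells$z_um, 1.75)
  expect_equal(cells$voxel_count, 2L)
  expect_equal(cells$volume_um3, 2 * 3.5)
  # empty mask -> empty table
  e <- extract_cells(mask_volume(array(0, c(4L, 4L, 4L))),
                     intensity_volume(array(1, c(4L, 4L, 4L))))
  expect_identical(nrow(e), 0L)
})

test_that("patch-wise inference stitches voxel-identically to whole-volume inference", {
  vol <- tiny_volume(c(40L, 40L, 40L), seed = 17, max_val = 500)
  seg <- threshold_segmenter(250)
  whole <- seg(vol$data)
  for (halo in c(0L, 4L, 8L)) {
    tiled <- segment_volume(seg, vol, core_shape = c(16L, 16L, 16L), halo = halo)
    expect_equal(tiled$data, whole, info = paste("halo", halo))
  }
  # determinism
  t1 <- segment_volume(seg, vol, c(16L, 16L, 16L), 4L)
  t2 <- segment_volume(seg, vol, c(16L, 16L, 16L), 4L)
  expect_identical(t1$data, t2$data)
})
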