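#' Estimate an intensity threshold from representative regions
#'
#' The spot-mask threshold is determined by statistical analysis of the
#' fluorescence intensity: `T = mean + k * SD` over the voxels pooled from
#' the supplied region boxes (population SD, matching a single pass over the
#' concatenated voxels).
#'
#' @param vol an [intensity_volume()].
#' @param region_boxes list of boxes, each `list(lo = c(z,y,x), hi = c(z,y,x))`
#'   in 0-based inclusive voxel coordinates; `NULL` uses the whole volume.
#' @param k SD multiplier (default 3, a classical z-cut).
#' @return a `threshold_report`: `threshold`, `mean`, `sd`, `k`, `n_voxels`
#'   and a per-box stats data frame.
#' @export
estimate_intensity_threshold <- function(vol, region_boxes = NULL, k = 3) {
  d <- dim(vol$data)
  if (is.null(region_boxes))
    region_boxes <- list(list(lo = c(0L, 0L, 0L), hi = d - 1L))
  if (length(region_boxes) == 0L) stop("at least one region box is required")
  vals <- list()
  per_box <- vector("list", length(region_boxes))
  for (i in seq_along(region_boxes)) {
    b <- region_boxes[[i]]
    lo <- as.integer(b$lo); hi <- as.integer(b$hi)
    if (any(lo < 0L) || any(hi > d - 1L)) stop("box outside volume")
    if (any(hi < lo)) stop("empty box")
    v <- vol$data[seq.int(lo[1], hi[1]) + 1L,
                  seq.int(lo[2], hi[2]) + 1L,
                  seq.int(lo[3], hi[3]) + 1L]
    vals[[i]] <- as.vector(v)
    per_box[[i]] <- data.frame(box = i, n = length(v), mean = mean(v),
                               sd = pop_sd(as.vector(v)))
  }
  pooled <- unlist(vals)
  m <- mean(pooled)
  s <- pop_sd(pooled)
  structure(list(threshold = m + k * s, mean = m, sd = s, k = k,
                 n_voxels = length(pooled),
                 boxes = do.call(rbind, per_box)),
            class = "threshold_report")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> T = %.4g (mean %.4g + %g x SD %.4g over %d voxels, %d boxes)\n",
              x$threshold, x$mean, x$k, x$sd, x$n_voxels, nrow(x$boxes)))
  invisible(x)
}

#' Detect spot peaks above a threshold
#'
#' Finds 26-neighbourhood local maxima with intensity >= `T` (ties with
#' neighbours count as candidates), then greedily suppresses peaks closer
#' than `min_separation_um` in physical distance, visiting candidates in
#' descending intensity with lexicographic `(z, y, x)` tie-break, so
#' detection is deterministic.
#'
#' @param vol an [intensity_volume()].
#' @param T intensity threshold (finite).
#' @param min_separation_um minimum physical distance between two peaks.
#' @return integer matrix of 0-based peak voxel coordinates, columns z,y,x
#'   (zero rows when nothing is detected).
#' @export
detect_spots <- function(vol, T, min_separation_um = 8) {
  stopifnot(is.finite(T), min_separation_um > 0)
  x <- vol$data
  d <- dim(x)
  is_max <- x >= T
  offsets <- neighbor_offsets_26()
  for (i in seq_len(nrow(offsets))) {
    if (!any(is_max)) break
    is_max <- is_max & (x >= shift_array(x, offsets[i, ], fill = -Inf))
  }
  cand <- which(is_max)
  if (length(cand) == 0L)
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  co <- arrayInd(cand, d) - 1L
  ord <- order(-x[cand], co[, 1], co[, 2], co[, 3])
  co <- co[ord, , drop = FALSE]
  vs <- vol$voxel_size
  co_um <- sweep(co, 2, vs, `*`)
  keep <- logical(nrow(co))
  acc <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(co))) {
    if (nrow(acc) == 0L ||
        min(rowSums(sweep(acc, 2, co_um[i, ])^2)) >= min_separation_um^2) {
      keep[i] <- TRUE
      acc <- rbind(acc, co_um[i, ])
    }
  }
  out <- co[keep, , drop = FALSE]
  out <- out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
  colnames(out) <- c("z", "y", "x")
  out
}

neighbor_offsets_26 <- function() {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ])
}

# shift array contents by (dz,dy,dx); vacated voxels take `fill`
shift_array <- function(x, off, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) {
      if (o >= d[a]) return(out)
      src[[a]] <- seq.int(1L, d[a] - o)
      dst[[a]] <- seq.int(1L + o, d[a])
    } else {
      if (-o >= d[a]) return(out)
      src[[a]] <- seq.int(1L - o, d[a])
      dst[[a]] <- seq.int(1L, d[a] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Render ellipsoidal spot masks at peak locations
#'
#' Each peak becomes an ellipsoid of physical radius `spot_radius_um`
#' (converted per axis by the voxel size); overlapping spots take the union
#' and out-of-volume portions are clipped.
#'
#' @param shape `(z, y, x)` output shape.
#' @param voxel_size `(dz, dy, dx)` um.
#' @param peaks 0-based integer matrix of peak voxels (columns z,y,x).
#' @param spot_radius_um ellipsoid radius in um (> 0).
#' @return a [mask_volume()].
#' @export
render_spot_mask <- function(shape, voxel_size, peaks, spot_radius_um = 3) {
  if (spot_radius_um <= 0) stop("spot radius must be positive")
  shape <- as.integer(shape)
  mask <- array(0, shape)
  if (NROW(peaks) > 0) {
    rv <- spot_radius_um / voxel_size
    for (i in seq_len(nrow(peaks))) {
      c_vox <- as.numeric(peaks[i, ])
      if (any(c_vox < 0) || any(c_vox > shape - 1))
        stop("peak outside volume bounds")
      lo <- pmax(floor(c_vox - rv), 0)
      hi <- pmin(ceiling(c_vox + rv), shape - 1)
      zz <- seq.int(lo[1], hi[1]); yy <- seq.int(lo[2], hi[2]); xx <- seq.int(lo[3], hi[3])
      e <- outer(outer(((zz - c_vox[1]) / rv[1])^2, ((yy - c_vox[2]) / rv[2])^2, `+`),
                 ((xx - c_vox[3]) / rv[3])^2, `+`) <= 1
      sub <- mask[zz + 1, yy + 1, xx + 1, drop = FALSE]
      mask[zz + 1, yy + 1, xx + 1] <- pmax(sub, e * 1)
    }
  }
  mask_volume(mask, voxel_size)
}

#' Build a training set of image/spot-mask patch pairs
#'
#' For every sample: estimate the intensity threshold, detect spot peaks,
#' render the spot mask, and tile image and mask into model-input patches
#' (halo 0). Samples with zero detected spots emit a warning but their
#' patches are kept (pure-background examples).
#'
#' @param samples list of phantom samples (elements with `$signal`) or
#'   [intensity_volume()]s.
#' @param config a pipeline config ([default_config()] subset used:
#'   `mask_generation`, `tile$core_shape`).
#' @param core_shape override of the training patch shape.
#' @return list with `pairs` (each `list(id, image, mask, source, origin,
#'   positive_fraction)`), `index` data frame and `positive_fraction`
#'   (rendered mask voxels / total voxels over the source volumes).
#' @export
build_training_set <- function(samples, config = default_config(),
                               core_shape = config$train$patch_shape) {
  stopifnot(length(samples) >= 1)
  mg <- config$mask_generation
  pairs <- list()
  index <- list()
  pos_vox <- 0; tot_vox <- 0
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    vol <- if (inherits(s, "intensity_volume")) s else s$signal
    rep_ <- estimate_intensity_threshold(vol, k = mg$k_thresh)
    peaks <- detect_spots(vol, rep_$threshold, mg$min_separation_um)
    if (nrow(peaks) == 0L)
      warning("sample ", si, ": zero detected spots; emitting background-only patches")
    mask <- render_spot_mask(dim(vol$data), vol$voxel_size, peaks,
                             mg$spot_radius_um)
    pos_vox <- pos_vox + sum(mask$data)
    tot_vox <- tot_vox + length(mask$data)
    img_tiles <- tile_volume(vol, core_shape, halo = 0L)
    mask_tiles <- tile_volume(mask, core_shape, halo = 0L)
    for (ti in seq_along(img_tiles)) {
      id <- sprintf("s%03d_p%04d", si, ti)
      pf <- mean(mask_tiles[[ti]]$data)
      pairs[[length(pairs) + 1L]] <- list(
        id = id, image = img_tiles[[ti]]$data, mask = mask_tiles[[ti]]$data,
        source = si, origin = img_tiles[[ti]]$spec$core_origin,
        positive_fraction = pf)
      index[[length(index) + 1L]] <- data.frame(
        patch_id = id, source = si,
        origin_z = img_tiles[[ti]]$spec$core_origin[1],
        origin_y = img_tiles[[ti]]$spec$core_origin[2],
        origin_x = img_tiles[[ti]]$spec$core_origin[3],
        positive_fraction = pf)
    }
  }
  list(pairs = pairs, index = do.call(rbind, index),
       positive_fraction = pos_vox / tot_vox)
}
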