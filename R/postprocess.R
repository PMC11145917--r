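#' 26-connected components of a binary mask
#'
#' Components are computed on the graph whose vertices are positive voxels
#' and whose edges join 26-adjacent positive voxels; component ids are
#' relabelled by ascending minimal linear voxel index so labelling is
#' deterministic.
#'
#' @param mask a [mask_volume()] or 0/1 array.
#' @return list: `n` components, `voxels` (list of linear indices per
#'   component), `dim` of the mask.
#' @keywords internal
connected_components_26 <- function(mask) {
  m <- if (is.list(mask)) mask$data else mask
  d <- dim(m)
  pos <- which(m == 1)
  if (length(pos) == 0L) return(list(n = 0L, voxels = list(), dim = d))
  rank_of <- array(0L, d)
  rank_of[pos] <- seq_along(pos)
  co <- arrayInd(pos, d)
  offs <- neighbor_offsets_26()
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    nb <- co
    nb[, 1] <- nb[, 1] + offs[i, 1]
    nb[, 2] <- nb[, 2] + offs[i, 2]
    nb[, 3] <- nb[, 3] + offs[i, 3]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_rank <- rank_of[nb_lin]
    hit <- nb_rank > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], nb_rank[hit])
  }
  g <- igraph::make_empty_graph(n = length(pos), directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  comp_voxels <- split(pos, memb)
  first <- vapply(comp_voxels, min, numeric(1))
  comp_voxels <- comp_voxels[order(first)]
  names(comp_voxels) <- NULL
  list(n = length(comp_voxels), voxels = comp_voxels, dim = d)
}

drop_components <- function(mask_data, comps, drop_idx) {
  if (length(drop_idx) > 0)
    mask_data[unlist(comps$voxels[drop_idx])] <- 0
  mask_data
}

#' Autofluorescence false-positive filter
#'
#' Removes 26-connected components of the signal-channel mask whose fraction
#' of voxels also positive in the autofluorescence-channel mask is at least
#' `overlap_frac` — broadband structures (vessels, debris) appear in both
#' channels, genuine c-Fos+ nuclei only in the signal channel.
#'
#' @param cfos_mask,af_mask [mask_volume()]s of identical shape.
#' @param overlap_frac removal threshold theta in (0, 1].
#' @return list `(mask, removed)`; `removed` is a data frame of the deleted
#'   components (voxel count, overlap fraction).
#' @export
autofluorescence_filter <- function(cfos_mask, af_mask, overlap_frac = 0.5) {
  if (!identical(dim(cfos_mask$data), dim(af_mask$data)))
    stop("shape mismatch between channel masks")
  stopifnot(overlap_frac > 0, overlap_frac <= 1)
  comps <- connected_components_26(cfos_mask)
  frac <- vapply(comps$voxels, function(v) mean(af_mask$data[v]), numeric(1))
  drop <- which(frac >= overlap_frac)
  out <- mask_volume(drop_components(cfos_mask$data, comps, drop),
                     cfos_mask$voxel_size)
  removed <- data.frame(component = drop,
                        voxel_count = vapply(comps$voxels[drop], length, integer(1)),
                        overlap_fraction = frac[drop],
                        reason = rep("autofluorescence", length(drop)))
  list(mask = out, removed = removed, n_components = comps$n)
}

#' Soma-size (no-soma object) filter
#'
#' Removes components whose physical volume lies outside `[vmin, vmax]` um^3:
#' sub-somatic specks (noise, debris) below, vessel fragments and clumps
#' above. Both bounds are closed (a component exactly at a bound is kept).
#'
#' @param mask a [mask_volume()].
#' @param vmin_um3,vmax_um3 soma volume bounds, `0 < vmin < vmax`.
#' @return list `(mask, removed)`.
#' @export
soma_filter <- function(mask, vmin_um3 = 50, vmax_um3 = 5000) {
  stopifnot(vmin_um3 > 0, vmax_um3 > vmin_um3)
  vox_um3 <- prod(mask$voxel_size)
  comps <- connected_components_26(mask)
  vol <- vapply(comps$voxels, length, integer(1)) * vox_um3
  drop <- which(vol < vmin_um3 | vol > vmax_um3)
  out <- mask_volume(drop_components(mask$data, comps, drop), mask$voxel_size)
  removed <- data.frame(component = drop,
                        voxel_count = vapply(comps$voxels[drop], length, integer(1)),
                        volume_um3 = vol[drop],
                        reason = rep("no_soma", length(drop)))
  list(mask = out, removed = removed, n_components = comps$n)
}

#' Intensity-based prediction filter
#'
#' Estimates robust background statistics over the voxels OUTSIDE the mask
#' (median m and MAD-derived sigma-hat = 1.4826 * MAD) and removes
#' components whose mean raw intensity is below `m + k * sigma-hat` —
#' predictions not supported by actual immunostaining signal.
#'
#' @param mask a [mask_volume()].
#' @param raw the matching raw [intensity_volume()].
#' @param k non-negative multiplier (default 3).
#' @return list `(mask, removed)`.
#' @export
intensity_filter <- function(mask, raw, k = 3) {
  if (!identical(dim(mask$data), dim(raw$data))) stop("shape mismatch")
  stopifnot(k >= 0)
  bg <- raw$data[mask$data == 0]
  if (length(bg) == 0L) stop("mask covers entire volume: no background voxels")
  m <- stats::median(bg)
  s <- stats::mad(bg)    # 1.4826 * MAD
  cut <- m + k * s
  comps <- connected_components_26(mask)
  mi <- vapply(comps$voxels, function(v) mean(raw$data[v]), numeric(1))
  drop <- which(mi < cut)
  out <- mask_volume(drop_components(mask$data, comps, drop), mask$voxel_size)
  removed <- data.frame(component = drop,
                        voxel_count = vapply(comps$voxels[drop], length, integer(1)),
                        mean_intensity = mi[drop],
                        reason = rep("intensity", length(drop)))
  list(mask = out, removed = removed, n_components = comps$n,
       background_median = m, background_sigma = s)
}

#' Run the dual-channel false-positive filter chain
#'
#' Autofluorescence filter, then soma-size filter, then intensity filter,
#' with exact removal accounting: components before minus the (disjoint)
#' removal sets equals components after.
#'
#' @param cfos_mask signal-channel [mask_volume()].
#' @param af_mask autofluorescence-channel [mask_volume()].
#' @param raw raw signal [intensity_volume()].
#' @param config pipeline config (`filters` section used).
#' @return list `(mask, report)`; `report` is a `filter_report`.
#' @export
apply_filter_chain <- function(cfos_mask, af_mask, raw,
                               config = default_config()) {
  fl <- config$filters
  before <- connected_components_26(cfos_mask)$n
  f1 <- autofluorescence_filter(cfos_mask, af_mask, fl$af_overlap_frac)
  f2 <- soma_filter(f1$mask, fl$soma_volume_um3_min, fl$soma_volume_um3_max)
  f3 <- intensity_filter(f2$mask, raw, fl$intensity_k)
  after <- connected_components_26(f3$mask)$n
  report <- structure(list(
    components_before = before,
    removed_autofluorescence = nrow(f1$removed),
    removed_no_soma = nrow(f2$removed),
    removed_intensity = nrow(f3$removed),
    components_after = after,
    details = list(autofluorescence = f1$removed, no_soma = f2$removed,
                   intensity = f3$removed)), class = "filter_report")
  stopifnot(before - report$removed_autofluorescence - report$removed_no_soma -
              report$removed_intensity == after)
  list(mask = f3$mask, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d components -> %d (removed: %d autofluorescence, %d no-soma, %d intensity)\n",
              x$components_before, x$components_after,
              x$removed_autofluorescence, x$removed_no_soma, x$removed_intensity))
  invisible(x)
}

#' Extract per-cell records from a mask
#'
#' Enumerates 26-connected components; the centroid is the intensity-weighted
#' centre of mass of the component voxels (0-based voxel coordinates, plus
#' micrometres). Cells are ordered by centroid `(z, y, x)` for determinism.
#'
#' @param mask a [mask_volume()].
#' @param raw the matching raw [intensity_volume()].
#' @return a `cell_table` data frame: cell_id, z/y/x_vox, z/y/x_um,
#'   voxel_count, volume_um3, mean_intensity, max_intensity, region_id (0 =
#'   unassigned), hemisphere.
#' @export
extract_cells <- function(mask, raw) {
  if (!identical(dim(mask$data), dim(raw$data))) stop("shape mismatch")
  comps <- connected_components_26(mask)
  vs <- mask$voxel_size
  n <- comps$n
  if (n == 0L) {
    out <- data.frame(cell_id = integer(0), z_vox = numeric(0),
                      y_vox = numeric(0), x_vox = numeric(0),
                      z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                      voxel_count = integer(0), volume_um3 = numeric(0),
                      mean_intensity = numeric(0), max_intensity = numeric(0),
                      region_id = integer(0), hemisphere = character(0))
    attr(out, "voxel_size") <- vs
    return(out)
  }
  rec <- matrix(NA_real_, n, 7)
  for (i in seq_len(n)) {
    v <- comps$voxels[[i]]
    co <- arrayInd(v, comps$dim) - 1L
    w <- raw$data[v]
    if (sum(w) == 0) w <- rep(1, length(v))
    cz <- sum(co[, 1] * w) / sum(w)
    cy <- sum(co[, 2] * w) / sum(w)
    cx <- sum(co[, 3] * w) / sum(w)
    rec[i, ] <- c(cz, cy, cx, length(v), mean(raw$data[v]), max(raw$data[v]), 0)
  }
  out <- data.frame(z_vox = rec[, 1], y_vox = rec[, 2], x_vox = rec[, 3],
                    voxel_count = as.integer(rec[, 4]),
                    mean_intensity = rec[, 5], max_intensity = rec[, 6])
  out$z_um <- out$z_vox * vs[1]
  out$y_um <- out$y_vox * vs[2]
  out$x_um <- out$x_vox * vs[3]
  out$volume_um3 <- out$voxel_count * prod(vs)
  out <- out[order(out$z_vox, out$y_vox, out$x_vox), ]
  out$cell_id <- seq_len(n)
  out$region_id <- 0L
  out$hemisphere <- "unassigned"
  rownames(out) <- NULL
  out <- out[, c("cell_id", "z_vox", "y_vox", "x_vox", "z_um", "y_um", "x_um",
                 "voxel_count", "volume_um3", "mean_intensity",
                 "max_intensity", "region_id", "hemisphere")]
  attr(out, "voxel_size") <- vs
  out
}

#' Segment a whole volume by tiled inference
#'
#' Tiles the volume (reflected halos), runs the segmenter on every patch,
#' crops halos and stitches the cores back — voxel-identical to segmenting
#' the whole volume at once for any voxel-wise deterministic segmenter.
#'
#' @param model a trained [hswin3d] model, or any function mapping a 3D
#'   patch array to a 0/1 array of the same shape (e.g.
#'   [threshold_segmenter()]).
#' @param vol an [intensity_volume()].
#' @param core_shape,halo tiling parameters.
#' @return a [mask_volume()] of the same shape as `vol`.
#' @export
segment_volume <- function(model, vol, core_shape = c(48L, 48L, 48L),
                           halo = 8L) {
  seg_fun <- if (is.function(model)) model else function(patch) {
    pr <- predict(model, patch)
    (pr[, , , 2] > pr[, , , 1]) * 1
  }
  patches <- tile_volume(vol, core_shape, halo)
  for (i in seq_along(patches)) {
    pred <- seg_fun(patches[[i]]$data)
    stopifnot(identical(dim(pred), dim(patches[[i]]$data)))
    patches[[i]]$data <- pred
  }
  stitch_masks(patches, dim(vol$data), vol$voxel_size)
}

#' Deterministic thresholding stand-in segmenter
#'
#' Returns a voxel-wise segmenter marking voxels strictly above `threshold`;
#' used as an analytic oracle for the tiling/stitching identity and for
#' noise-free phantom studies.
#'
#' @param threshold absolute intensity cut.
#' @return function(patch array) -> 0/1 array.
#' @export
threshold_segmenter <- function(threshold) {
  force(threshold)
  function(patch) (patch > threshold) * 1
}
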