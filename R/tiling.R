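#' Mirror-reflected index lookup
#'
#' Maps any integer index (0-based) onto `0..(n-1)` by repeated reflection
#' about the first and last sample (no edge duplication), the padding mode
#' used for tiling so that attention/convolution see no artificial edges.
#'
#' @keywords internal
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  period <- 2L * (n - 1L)
  m <- ((i %% period) + period) %% period
  ifelse(m < n, m, period - m)
}

pad_reflect <- function(data, before, after) {
  d <- dim(data)
  iz <- reflect_index(seq.int(-before[1], d[1] - 1L + after[1]), d[1]) + 1L
  iy <- reflect_index(seq.int(-before[2], d[2] - 1L + after[2]), d[2]) + 1L
  ix <- reflect_index(seq.int(-before[3], d[3] - 1L + after[3]), d[3]) + 1L
  data[iz, iy, ix, drop = FALSE]
}

#' Tile a volume into overlapping patches
#'
#' Core regions partition the volume exactly (edge cores are clipped); each
#' patch datum has shape `core_shape + 2 * halo`, with out-of-volume voxels
#' filled by mirror reflection.
#'
#' @param vol an [intensity_volume()] or [mask_volume()].
#' @param core_shape length-3 integer `(z, y, x)` core tile shape.
#' @param halo non-negative integer, halo voxels per side (same on all axes).
#' @return list of patches, each `list(spec, data)`; `spec` holds
#'   `core_origin` (0-based), `core_extent` (clipped), `core_shape` (nominal)
#'   and `halo`.
#' @export
tile_volume <- function(vol, core_shape, halo = 0L) {
  core_shape <- as.integer(core_shape)
  halo <- as.integer(halo)
  if (length(core_shape) != 3L || any(core_shape < 1L))
    stop("core_shape components must be >= 1")
  if (length(halo) != 1L || halo < 0L) stop("halo must be a non-negative integer")
  d <- dim(vol$data)
  origins <- lapply(1:3, function(a) seq.int(0L, d[a] - 1L, by = core_shape[a]))
  grid <- expand.grid(z = origins[[1]], y = origins[[2]], x = origins[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  # pad once: halo before, halo + (cover overhang) after
  cover <- vapply(1:3, function(a) max(origins[[a]]) + core_shape[a] - d[a],
                  numeric(1))
  padded <- pad_reflect(vol$data, rep(halo, 3), cover + halo)
  patches <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    o <- as.integer(grid[i, c("z", "y", "x")])
    extent <- pmin(core_shape, d - o)
    idx <- lapply(1:3, function(a) seq.int(o[a] + 1L, o[a] + core_shape[a] + 2L * halo))
    patches[[i]] <- list(
      spec = list(core_origin = o, core_extent = extent,
                  core_shape = core_shape, halo = halo),
      data = padded[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  patches
}

#' Stitch patch masks back into a full volume
#'
#' Only the halo-cropped core region of each patch is written; the patch
#' specs must tile `full_shape` exactly (each voxel written exactly once).
#'
#' @param patches list of `list(spec, data)` as produced by [tile_volume()]
#'   (data may have been replaced by per-patch predictions of equal shape).
#' @param full_shape length-3 integer target shape `(z, y, x)`.
#' @param voxel_size voxel size for the output mask.
#' @return a [mask_volume()].
#' @export
stitch_masks <- function(patches, full_shape, voxel_size = c(3.5, 1, 1)) {
  full_shape <- as.integer(full_shape)
  out <- array(0, full_shape)
  hits <- array(0L, full_shape)
  for (p in patches) {
    s <- p$spec
    o <- s$core_origin
    e <- s$core_extent
    h <- s$halo
    core <- p$data[seq.int(h + 1L, h + e[1]),
                   seq.int(h + 1L, h + e[2]),
                   seq.int(h + 1L, h + e[3]), drop = FALSE]
    zi <- seq.int(o[1] + 1L, o[1] + e[1])
    yi <- seq.int(o[2] + 1L, o[2] + e[2])
    xi <- seq.int(o[3] + 1L, o[3] + e[3])
    if (any(hits[zi, yi, xi] > 0L)) stop("overlapping tiling: voxel written twice")
    out[zi, yi, xi] <- core
    hits[zi, yi, xi] <- 1L
  }
  if (any(hits == 0L)) stop("incomplete tiling: uncovered voxels remain")
  mask_volume(out, voxel_size = voxel_size)
}
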