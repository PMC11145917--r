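#' Intensity volumes
#'
#' A 3D single-channel imaging volume with anisotropic physical voxel size.
#' Data are stored as an array with dimensions ordered `(z, y, x)`; voxel
#' indices in all public tables are 0-based and physical coordinates are
#' `index * voxel_size` micrometres.
#'
#' @param data numeric 3D array, non-negative intensities (arbitrary units).
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in micrometres.
#' @param channel `"signal"` (c-Fos) or `"autofluorescence"`.
#' @return an object of class `intensity_volume`.
#' @export
intensity_volume <- function(data, voxel_size = c(3.5, 1, 1),
                             channel = c("signal", "autofluorescence")) {
  channel <- match.arg(channel)
  data <- as_volume_array(data)
  if (any(data < 0)) stop("intensity volume must be non-negative")
  check_voxel_size(voxel_size)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 channel = channel),
            class = "intensity_volume")
}

#' Binary mask volumes
#'
#' A voxel-wise binary segmentation aligned to an [intensity_volume()].
#'
#' @param data 3D array of 0/1 (logical arrays are coerced).
#' @param voxel_size numeric length-3 `(dz, dy, dx)` in micrometres.
#' @return an object of class `mask_volume`.
#' @export
mask_volume <- function(data, voxel_size = c(3.5, 1, 1)) {
  data <- as_volume_array(data)
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  check_voxel_size(voxel_size)
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "mask_volume")
}

as_volume_array <- function(data) {
  if (is.logical(data)) data <- data * 1
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  storage.mode(data) <- "double"
  data
}

check_voxel_size <- function(voxel_size) {
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (dz, dy, dx)")
  invisible(TRUE)
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<intensity_volume> %s channel, %d x %d x %d voxels (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_volume> %d x %d x %d voxels (z,y,x), %d positive (%.3g%%)\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

MAX_UINT16 <- 65535

#' Read a volume from a multi-page TIFF or a directory of per-plane TIFFs
#'
#' Planes are stacked along z; for a directory, files are taken in
#' lexicographic order. Pixels must be stored as integers (unsigned 16-bit is
#' the working format produced by [write_volume()]).
#'
#' @param path a multi-page TIFF file, or a directory of single-plane TIFFs.
#' @param channel channel label for the resulting volume.
#' @param voxel_size `(dz, dy, dx)` in micrometres (sidecar metadata is not
#'   parsed; the caller supplies the calibration, typically from the config).
#' @return an [intensity_volume()], data shape `(n_planes, H, W)`.
#' @export
read_volume <- function(path, channel = "signal", voxel_size = c(3.5, 1, 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  planes <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF planes found in directory: ", path)
    lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    p <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(p)) list(p) else p
  }
  shapes <- vapply(planes, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent plane shapes")
  if (any(vapply(planes, function(p) any(p != round(p)), logical(1))))
    stop("non-integer pixel type; expected an integer-valued TIFF")
  nz <- length(planes)
  arr <- array(0, c(nz, shapes[1, 1], shapes[2, 1]))
  for (z in seq_len(nz)) arr[z, , ] <- planes[[z]]
  intensity_volume(arr, voxel_size = voxel_size, channel = channel)
}

#' Write a volume as an unsigned 16-bit multi-page TIFF
#'
#' @param vol an [intensity_volume()] or [mask_volume()] (masks are written
#'   as 0/1); intensities are clamped to the 16-bit range.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  data <- round(vol$data)
  if (any(data < 0) || any(data > MAX_UINT16))
    stop("intensities outside the unsigned 16-bit range")
  planes <- lapply(seq_len(dim(data)[1]),
                   function(z) data[z, , , drop = TRUE] / MAX_UINT16)
  planes <- lapply(planes, function(p) {
    if (is.null(dim(p))) matrix(p, dim(data)[2], dim(data)[3]) else p
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}
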