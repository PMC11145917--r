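#' Specification of a synthetic dual-channel phantom
#'
#' The phantom emulates light-sheet imaging of immunostained tissue:
#' sparse bright soma-scale spots (c-Fos+ nuclei) in the signal channel,
#' broadband autofluorescent vessel-like tubes visible in both channels,
#' and Gaussian background noise on an anisotropic voxel grid.
#'
#' @param shape `(z, y, x)` voxel dimensions.
#' @param voxel_size `(dz, dy, dx)` um; default 3.5 x 1 x 1 matches
#'   high-speed volumetric light-sheet acquisition.
#' @param n_cells number of spot-like cells.
#' @param cell_radius_um range of cell radii (uniform draw).
#' @param cell_peak_intensity range of peak amplitudes above background.
#' @param background_level constant background (a.u.).
#' @param noise_sd Gaussian noise SD added last to both channels.
#' @param n_vessels number of random-walk vessel tubes.
#' @param vessel_radius_um tube radius.
#' @param vessel_intensity tube amplitude in the autofluorescence channel.
#' @param autofl_bleed_frac fraction of vessel intensity bleeding into the
#'   signal channel (vessels are broadband, cells are not).
#' @param seed RNG seed; the phantom is a deterministic function of the spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 128L, 128L), voxel_size = c(3.5, 1, 1),
                         n_cells = 80L, cell_radius_um = c(2, 4),
                         cell_peak_intensity = c(300, 600),
                         background_level = 100, noise_sd = 5,
                         n_vessels = 4L, vessel_radius_um = 3,
                         vessel_intensity = 300, autofl_bleed_frac = 0.6,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
               n_cells = as.integer(n_cells),
               cell_radius_um = as.numeric(cell_radius_um),
               cell_peak_intensity = as.numeric(cell_peak_intensity),
               background_level = background_level, noise_sd = noise_sd,
               n_vessels = as.integer(n_vessels),
               vessel_radius_um = vessel_radius_um,
               vessel_intensity = vessel_intensity,
               autofl_bleed_frac = autofl_bleed_frac, seed = as.integer(seed))
  stopifnot(spec$n_cells >= 0, spec$n_vessels >= 0,
            all(spec$cell_radius_um > 0), spec$vessel_radius_um > 0,
            spec$autofl_bleed_frac >= 0, spec$autofl_bleed_frac <= 1,
            spec$noise_sd >= 0)
  check_voxel_size(spec$voxel_size)
  structure(spec, class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# truncation radius of the rendered Gaussian spot, in multiples of sigma
SPOT_TRUNC_SIGMA <- 2.5

#' Generate a dual-channel phantom with exact ground truth
#'
#' Vessels are laid down first as smoothed random-walk tubes (rendered into
#' both channels); cells are then placed with a margin from volume borders,
#' from each other and from vessels, so that the ground-truth count is exact
#' and no spot is clipped. Cells are isotropic-in-um Gaussian spots
#' (`sigma = radius / 2`) sampled on the anisotropic grid, truncated at
#' 2.5 sigma, and appear in the signal channel only.
#'
#' @param spec a [phantom_spec()].
#' @return list with `signal` and `autofl` ([intensity_volume()]s),
#'   `truth_cells` (data frame: 0-based voxel-space and um centroids,
#'   radius, peak) and `truth_vessel_mask` ([mask_volume()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$shape
    vs <- spec$voxel_size
    ext_um <- (d - 1) * vs   # coordinate of the last voxel in um
    signal <- array(0, d)
    autofl <- array(0, d)
    vessel_mask <- array(0, d)

    vessel_points <- matrix(numeric(0), ncol = 3)
    if (spec$n_vessels > 0) {
      for (v in seq_len(spec$n_vessels)) {
        pts <- vessel_walk(ext_um, step_um = 2, max_len_um = 1.5 * sqrt(sum(ext_um^2)))
        vessel_points <- rbind(vessel_points, pts)
        stamp_tube(vessel_mask, pts, spec$vessel_radius_um, vs) -> vessel_mask
      }
      autofl <- autofl + spec$vessel_intensity * vessel_mask
      signal <- signal + spec$autofl_bleed_frac * spec$vessel_intensity * vessel_mask
    }

    # cell placement with margins guaranteeing exact, unclipped ground truth
    r_max <- max(spec$cell_radius_um)
    extent_max <- SPOT_TRUNC_SIGMA * r_max / 2
    margin <- extent_max + vs            # per-axis margin in um
    min_sep <- 2 * extent_max + 2        # centre-to-centre separation
    if (any(2 * margin >= ext_um) && spec$n_cells > 0)
      stop("cell count infeasible for volume: placement margin exceeds volume")
    centers <- matrix(NA_real_, spec$n_cells, 3)
    radii <- peaks <- numeric(spec$n_cells)
    placed <- 0L
    tries <- 0L
    max_tries <- 400L * max(1L, spec$n_cells)
    while (placed < spec$n_cells) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("cell count infeasible for volume: placement failed after bounded retries")
      p <- margin + stats::runif(3) * (ext_um - 2 * margin)
      ok <- TRUE
      if (placed > 0) {
        dp <- sweep(centers[seq_len(placed), , drop = FALSE], 2, p)
        if (min(rowSums(dp^2)) < min_sep^2) ok <- FALSE
      }
      if (ok && nrow(vessel_points) > 0) {
        dv <- sweep(vessel_points, 2, p)
        if (min(rowSums(dv^2)) < (extent_max + spec$vessel_radius_um + 2)^2) ok <- FALSE
      }
      if (!ok) next
      placed <- placed + 1L
      centers[placed, ] <- p
      radii[placed] <- stats::runif(1, spec$cell_radius_um[1], spec$cell_radius_um[2])
      peaks[placed] <- stats::runif(1, spec$cell_peak_intensity[1],
                                    spec$cell_peak_intensity[2])
    }
    for (i in seq_len(spec$n_cells))
      signal <- stamp_gaussian(signal, centers[i, ], radii[i], peaks[i], vs)

    signal <- signal + spec$background_level
    autofl <- autofl + spec$background_level
    if (spec$noise_sd > 0) {
      signal <- signal + stats::rnorm(length(signal), 0, spec$noise_sd)
      autofl <- autofl + stats::rnorm(length(autofl), 0, spec$noise_sd)
    }
    signal <- round(pmax(signal, 0))
    autofl <- round(pmax(autofl, 0))

    truth <- data.frame(
      z_um = centers[, 1][seq_len(spec$n_cells)],
      y_um = centers[, 2][seq_len(spec$n_cells)],
      x_um = centers[, 3][seq_len(spec$n_cells)],
      radius_um = radii, peak = peaks)
    truth$z_vox <- truth$z_um / vs[1]
    truth$y_vox <- truth$y_um / vs[2]
    truth$x_vox <- truth$x_um / vs[3]

    list(signal = intensity_volume(array(signal, d), vs, "signal"),
         autofl = intensity_volume(array(autofl, d), vs, "autofluorescence"),
         truth_cells = truth,
         truth_vessel_mask = mask_volume(array(vessel_mask, d), vs))
  })
}

vessel_walk <- function(ext_um, step_um, max_len_um) {
  p <- stats::runif(3) * ext_um
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  n_steps <- ceiling(max_len_um / step_um)
  pts <- matrix(NA_real_, n_steps, 3)
  k <- 0L
  for (s in seq_len(n_steps)) {
    if (any(p < 0) || any(p > ext_um)) break
    k <- k + 1L
    pts[k, ] <- p
    dir <- dir + stats::rnorm(3, 0, 0.25)
    dir <- dir / sqrt(sum(dir^2))
    p <- p + step_um * dir
  }
  pts[seq_len(k), , drop = FALSE]
}

stamp_tube <- function(mask, pts, radius_um, vs) {
  d <- dim(mask)
  rv <- radius_um / vs
  for (i in seq_len(nrow(pts))) {
    c_vox <- pts[i, ] / vs
    lo <- pmax(floor(c_vox - rv), 0)
    hi <- pmin(ceiling(c_vox + rv), d - 1)
    if (any(lo > hi)) next
    zz <- seq.int(lo[1], hi[1]); yy <- seq.int(lo[2], hi[2]); xx <- seq.int(lo[3], hi[3])
    dz2 <- ((zz - c_vox[1]) * vs[1])^2
    dy2 <- ((yy - c_vox[2]) * vs[2])^2
    dx2 <- ((xx - c_vox[3]) * vs[3])^2
    ball <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= radius_um^2
    sub <- mask[zz + 1, yy + 1, xx + 1, drop = FALSE]
    mask[zz + 1, yy + 1, xx + 1] <- pmax(sub, ball * 1)
  }
  mask
}

stamp_gaussian <- function(vol, center_um, radius_um, peak, vs) {
  d <- dim(vol)
  sigma <- radius_um / 2
  ext <- SPOT_TRUNC_SIGMA * sigma
  c_vox <- center_um / vs
  lo <- pmax(floor(c_vox - ext / vs), 0)
  hi <- pmin(ceiling(c_vox + ext / vs), d - 1)
  zz <- seq.int(lo[1], hi[1]); yy <- seq.int(lo[2], hi[2]); xx <- seq.int(lo[3], hi[3])
  dz2 <- ((zz - c_vox[1]) * vs[1])^2
  dy2 <- ((yy - c_vox[2]) * vs[2])^2
  dx2 <- ((xx - c_vox[3]) * vs[3])^2
  d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  spot <- peak * exp(-d2 / (2 * sigma^2))
  spot[d2 > ext^2] <- 0
  vol[zz + 1, yy + 1, xx + 1] <- vol[zz + 1, yy + 1, xx + 1] + spot
  vol
}
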