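#' Affine image-to-atlas transforms
#'
#' A 4x4 homogeneous matrix mapping image physical coordinates (um, ordered
#' z,y,x) to atlas voxel coordinates (0-based, ordered z,y,x). Registration
#' itself is out of scope: the transform is an input, typically produced by
#' an external whole-brain alignment.
#'
#' @param scale length-3 scale (um -> atlas voxel), e.g. `1 / atlas voxel size`.
#' @param translation length-3 offset in atlas voxels.
#' @return 4x4 matrix of class `affine_transform`.
#' @export
make_affine <- function(scale = c(1, 1, 1), translation = c(0, 0, 0)) {
  m <- diag(4)
  diag(m)[1:3] <- scale
  m[1:3, 4] <- translation
  class(m) <- c("affine_transform", "matrix")
  m
}

check_affine <- function(T) {
  if (!all(dim(T) == c(4, 4)) || any(T[4, ] != c(0, 0, 0, 1)))
    stop("transform must be 4x4 homogeneous with last row (0,0,0,1)")
  if (abs(det(T)) < 1e-12) stop("singular transform")
  invisible(TRUE)
}

apply_affine <- function(T, pts_um) {
  check_affine(T)
  h <- cbind(pts_um, 1)
  out <- h %*% t(T)
  out[, 1:3, drop = FALSE]
}

#' Map cells into atlas space
#'
#' Transforms each cell centroid (um) to atlas voxel coordinates, rounds to
#' the nearest voxel (no label interpolation) and assigns `region_id` from
#' the annotation (0 when outside the annotation or outside the brain).
#' The hemisphere is assigned from the atlas coordinate on the mediolateral
#' axis: below the midline index = `"L"`, at or above = `"R"` (ties to R);
#' unassigned cells keep `"unassigned"`.
#'
#' @param cells a `cell_table` from [extract_cells()].
#' @param T an [make_affine()] transform (image um -> atlas voxel).
#' @param atlas an `atlas_bundle`.
#' @return `cells` with `atlas_z/y/x`, `region_id` and `hemisphere` filled.
#' @export
map_cells_to_atlas <- function(cells, T, atlas) {
  if (nrow(cells) == 0L) {
    cells$atlas_z <- cells$atlas_y <- cells$atlas_x <- integer(0)
    return(cells)
  }
  pts <- apply_affine(T, as.matrix(cells[, c("z_um", "y_um", "x_um")]))
  vox <- round(pts)
  d <- dim(atlas$annotation)
  inb <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  region <- integer(nrow(cells))
  lin <- (vox[inb, 1] + 1) + vox[inb, 2] * d[1] + vox[inb, 3] * d[1] * d[2]
  region[inb] <- atlas$annotation[lin]
  cells$atlas_z <- as.integer(vox[, 1])
  cells$atlas_y <- as.integer(vox[, 2])
  cells$atlas_x <- as.integer(vox[, 3])
  cells$region_id <- as.integer(region)
  hemi <- rep("unassigned", nrow(cells))
  ml <- vox[, atlas$midline_axis]
  hemi[region > 0 & ml < atlas$midline_index] <- "L"
  hemi[region > 0 & ml >= atlas$midline_index] <- "R"
  cells$hemisphere <- hemi
  cells
}

# ancestor of each ontology node at a requested level (id -> ancestor id or NA)
ancestors_at_level <- function(ontology, level) {
  res <- setNames(rep(NA_integer_, nrow(ontology)), ontology$id)
  for (i in seq_len(nrow(ontology))) {
    id <- ontology$id[i]
    cur <- id
    repeat {
      row <- match(cur, ontology$id)
      if (is.na(row)) break
      if (ontology$level[row] == level) { res[as.character(id)] <- cur; break }
      if (ontology$level[row] < level) break
      cur <- ontology$parent_id[row]
      if (is.na(cur)) break
    }
  }
  res
}

# descendant leaf (annotated) label ids of a node, itself included if annotated
descendant_labels <- function(atlas, node_id) {
  ont <- atlas$ontology
  wanted <- node_id
  repeat {
    kids <- ont$id[!is.na(ont$parent_id) & ont$parent_id %in% wanted &
                     !ont$id %in% wanted]
    if (length(kids) == 0) break
    wanted <- c(wanted, kids)
  }
  labels <- sort(unique(as.vector(atlas$annotation)))
  intersect(wanted, labels[labels > 0])
}

#' Per-region cell counts at an ontology level
#'
#' Each assigned cell is attributed to its annotated region's ancestor at
#' the requested level; counts, region volumes (annotated voxels times
#' voxel volume) and densities are computed per animal. Cells with
#' `region_id = 0` (and cells whose region has no ancestor at the level)
#' are excluded and reported in `attr(, "unassigned")`.
#'
#' @param cells `cell_table` (optionally with an `animal` column).
#' @param atlas an `atlas_bundle`.
#' @param level ontology level (must exist).
#' @param mask optional [mask_volume()] in atlas space (same shape as the
#'   annotation); fills the `volume_ratio` column (mask-positive volume in
#'   the region divided by region volume).
#' @return `region_count_table` data frame: animal, region_id, acronym,
#'   level, count, region_volume_mm3, density_per_mm3, volume_ratio.
#' @export
counts_by_level <- function(cells, atlas, level, mask = NULL) {
  ont <- atlas$ontology
  if (!level %in% ont$level) stop("level not present in ontology")
  anc <- ancestors_at_level(ont, level)
  regions <- sort(unique(as.integer(anc[!is.na(anc)])))
  if (nrow(cells) > 0 && any(cells$region_id > 0 &
                             !cells$region_id %in% ont$id))
    stop("unknown region id in cell table")
  animal <- if ("animal" %in% names(cells)) cells$animal else
    rep("A1", nrow(cells))
  animals <- if (length(animal) > 0) sort(unique(animal)) else "A1"
  # voxel counts per annotated label, aggregated to the level
  lab_tab <- table(atlas$annotation[atlas$annotation > 0])
  lab_ids <- as.integer(names(lab_tab))
  lab_anc <- anc[as.character(lab_ids)]
  vol_by_region <- tapply(as.numeric(lab_tab), lab_anc, sum)
  vox_mm3 <- prod(atlas$voxel_size) * 1e-9
  ratio_by_region <- NULL
  if (!is.null(mask)) {
    md <- if (is.list(mask)) mask$data else mask
    if (!identical(dim(md), dim(atlas$annotation)))
      stop("mask must match the annotation shape")
    pos_tab <- tapply(as.numeric(md[atlas$annotation > 0]),
                      atlas$annotation[atlas$annotation > 0], sum)
    pos_anc <- anc[names(pos_tab)]
    ratio_by_region <- tapply(as.numeric(pos_tab), pos_anc, sum)
  }
  rows <- list()
  unassigned <- 0L
  for (a in animals) {
    sel <- animal == a
    cr <- cells$region_id[sel]
    cr_anc <- rep(NA_integer_, length(cr))
    pos <- cr > 0
    cr_anc[pos] <- as.integer(anc[as.character(cr[pos])])
    unassigned <- unassigned + sum(!pos | is.na(cr_anc))
    cnt <- table(factor(cr_anc[!is.na(cr_anc)], levels = regions))
    vol_mm3 <- as.numeric(vol_by_region[as.character(regions)]) * vox_mm3
    vr <- if (is.null(ratio_by_region)) NA_real_ else {
      pr <- ratio_by_region[as.character(regions)]
      pr[is.na(pr)] <- 0
      as.numeric(pr) / as.numeric(vol_by_region[as.character(regions)])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      animal = a, region_id = regions,
      acronym = ont$acronym[match(regions, ont$id)], level = level,
      count = as.integer(cnt), region_volume_mm3 = vol_mm3,
      density_per_mm3 = as.integer(cnt) / vol_mm3,
      volume_ratio = vr)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  out
}

#' Layer-resolved counts, densities and volume ratios
#'
#' For each layer-tagged child of `parent_region`: cell count, density
#' (count / layer volume in mm^3) and volume ratio (mask-positive voxel
#' volume within the layer / layer volume).
#'
#' @param cells mapped `cell_table`.
#' @param mask [mask_volume()] in atlas space (or NULL: ratios 0).
#' @param atlas an `atlas_bundle` built `with_layers`.
#' @param parent_region id of the parent (leaf area) whose layers to report.
#' @return data frame: layer, region_id, count, volume_mm3, density_per_mm3,
#'   volume_ratio.
#' @export
layer_metrics <- function(cells, mask, atlas, parent_region) {
  ont <- atlas$ontology
  kids <- ont[!is.na(ont$parent_id) & ont$parent_id == parent_region &
                !is.na(ont$layer), ]
  if (nrow(kids) == 0) stop("parent region has no layer-tagged children")
  vox_mm3 <- prod(atlas$voxel_size) * 1e-9
  md <- if (is.null(mask)) NULL else if (is.list(mask)) mask$data else mask
  out <- data.frame(layer = kids$layer, region_id = kids$id,
                    count = NA_integer_, volume_mm3 = NA_real_,
                    density_per_mm3 = NA_real_, volume_ratio = NA_real_)
  for (i in seq_len(nrow(kids))) {
    sel_vox <- atlas$annotation == kids$id[i]
    nv <- sum(sel_vox)
    out$count[i] <- sum(cells$region_id == kids$id[i])
    out$volume_mm3[i] <- nv * vox_mm3
    out$density_per_mm3[i] <- out$count[i] / out$volume_mm3[i]
    out$volume_ratio[i] <- if (is.null(md)) 0 else sum(md[sel_vox]) / nv
  }
  out
}

#' Left/right hemisphere counts per region
#'
#' @param cells mapped `cell_table` (hemisphere assigned).
#' @param atlas an `atlas_bundle`.
#' @param level ontology level for aggregation.
#' @return data frame: region_id, acronym, count_L, count_R, count_total.
#' @export
hemisphere_counts <- function(cells, atlas, level) {
  ont <- atlas$ontology
  anc <- ancestors_at_level(ont, level)
  regions <- sort(unique(as.integer(anc[!is.na(anc)])))
  cr <- cells$region_id
  pos <- cr > 0
  cr_anc <- rep(NA_integer_, length(cr))
  cr_anc[pos] <- as.integer(anc[as.character(cr[pos])])
  f <- factor(cr_anc, levels = regions)
  cl <- table(f[cells$hemisphere == "L"])
  cr_ <- table(f[cells$hemisphere == "R"])
  data.frame(region_id = regions,
             acronym = ont$acronym[match(regions, ont$id)],
             count_L = as.integer(cl), count_R = as.integer(cr_),
             count_total = as.integer(cl) + as.integer(cr_))
}

#' Anterior-posterior profile of a region
#'
#' The region's annotated extent along the AP axis is split into `n_bins`
#' equal half-open bins `[a, b)` (last bin closed); per-animal cell counts
#' are tallied per bin using the cells' atlas coordinates.
#'
#' @param cells mapped `cell_table` (needs `atlas_z/y/x`).
#' @param atlas an `atlas_bundle`.
#' @param region region id (any level; descendants are included).
#' @param n_bins number of bins (>= 2).
#' @return data frame: animal, bin, ap_lo, ap_hi, count.
#' @export
ap_profile <- function(cells, atlas, region, n_bins) {
  stopifnot(n_bins >= 2)
  labels <- descendant_labels(atlas, region)
  sel_vox <- which(array(atlas$annotation %in% labels, dim(atlas$annotation)))
  if (length(sel_vox) == 0) stop("region has zero annotated voxels")
  ap <- atlas$ap_axis
  co <- arrayInd(sel_vox, dim(atlas$annotation)) - 1L
  lo <- min(co[, ap]); hi <- max(co[, ap])
  breaks <- seq(lo, hi + 1, length.out = n_bins + 1)
  in_region <- cells$region_id %in% labels
  animal <- if ("animal" %in% names(cells)) cells$animal else
    rep("A1", nrow(cells))
  animals <- sort(unique(animal[in_region]))
  if (length(animals) == 0) animals <- "A1"
  ap_coord <- cells[[c("atlas_z", "atlas_y", "atlas_x")[ap]]]
  rows <- list()
  for (a in animals) {
    sel <- in_region & animal == a
    bin <- findInterval(ap_coord[sel], breaks, rightmost.closed = TRUE)
    bin <- pmin(pmax(bin, 1L), n_bins)
    cnt <- table(factor(bin, levels = seq_len(n_bins)))
    rows[[length(rows) + 1L]] <- data.frame(
      animal = a, bin = seq_len(n_bins),
      ap_lo = breaks[-length(breaks)], ap_hi = breaks[-1],
      count = as.integer(cnt))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
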