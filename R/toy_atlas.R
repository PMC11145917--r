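#' Generate a toy hierarchical brain atlas
#'
#' Builds a nested rectangular partition of a "brain" box inside the volume
#' (a one-voxel rim of label 0 marks outside-brain), together with a rooted
#' ontology tree mimicking a structure graph: root (level 1) ->
#' superregions (level 2, slabs along y) -> leaf areas (level 3, slabs
#' along z). With `with_layers`, each leaf is further split into `n_layers`
#' slabs along z tagged `"L1"..` (level 4), and the annotation labels become
#' the layer leaves.
#'
#' @param shape `(z, y, x)` annotation dimensions.
#' @param n_superregions number of level-2 regions.
#' @param n_children_per leaf areas per superregion.
#' @param with_layers split each leaf into layer slabs.
#' @param n_layers layers per leaf (2..6) when `with_layers`.
#' @param voxel_size atlas voxel size in um (default isotropic 25 um).
#' @param seed unused randomness guard (the partition is deterministic);
#'   kept so bundles record provenance.
#' @return an `atlas_bundle`: `annotation` (integer array), `ontology`
#'   (data frame: id, acronym, name, parent_id, level, layer), `voxel_size`,
#'   `midline_axis` (= 3, the x axis), `midline_index`, `ap_axis` (= 1, z).
#' @export
generate_toy_atlas <- function(shape = c(32L, 64L, 64L), n_superregions = 2L,
                               n_children_per = 2L, with_layers = FALSE,
                               n_layers = 3L, voxel_size = c(25, 25, 25),
                               seed = 1L) {
  shape <- as.integer(shape)
  n_superregions <- as.integer(n_superregions)
  n_children_per <- as.integer(n_children_per)
  n_layers <- as.integer(n_layers)
  if (with_layers && (n_layers < 2L || n_layers > 6L))
    stop("n_layers must be in 2..6")
  brain_lo <- c(1L, 1L, 1L)            # 0-based inclusive bounds of the brain box
  brain_hi <- shape - 2L
  inner <- brain_hi - brain_lo + 1L
  n_z_slabs <- n_children_per * (if (with_layers) n_layers else 1L)
  if (inner[2] < n_superregions || inner[1] < n_z_slabs || any(inner < 1L))
    stop("infeasible partition: volume too small for requested atlas")

  ontology <- data.frame(id = 1L, acronym = "root", name = "root",
                         parent_id = NA_integer_, level = 1L,
                         layer = NA_character_, stringsAsFactors = FALSE)
  annotation <- array(0L, shape)
  next_id <- 2L
  y_edges <- slab_edges(brain_lo[2], brain_hi[2], n_superregions)
  for (s in seq_len(n_superregions)) {
    sup_id <- next_id; next_id <- next_id + 1L
    ontology <- rbind(ontology, data.frame(
      id = sup_id, acronym = paste0("SR", s), name = paste0("superregion ", s),
      parent_id = 1L, level = 2L, layer = NA_character_))
    z_edges <- slab_edges(brain_lo[1], brain_hi[1], n_children_per)
    for (k in seq_len(n_children_per)) {
      leaf_id <- next_id; next_id <- next_id + 1L
      ontology <- rbind(ontology, data.frame(
        id = leaf_id, acronym = paste0("SR", s, ".", k),
        name = paste0("area ", s, ".", k),
        parent_id = sup_id, level = 3L, layer = NA_character_))
      zi <- seq.int(z_edges[k], z_edges[k + 1] - 1L)
      yi <- seq.int(y_edges[s], y_edges[s + 1] - 1L)
      xi <- seq.int(brain_lo[3], brain_hi[3])
      if (!with_layers) {
        annotation[zi + 1L, yi + 1L, xi + 1L] <- leaf_id
      } else {
        l_edges <- slab_edges(z_edges[k], z_edges[k + 1] - 1L, n_layers)
        for (l in seq_len(n_layers)) {
          lay_id <- next_id; next_id <- next_id + 1L
          ontology <- rbind(ontology, data.frame(
            id = lay_id, acronym = paste0("SR", s, ".", k, "L", l),
            name = paste0("area ", s, ".", k, " layer ", l),
            parent_id = leaf_id, level = 4L, layer = paste0("L", l)))
          li <- seq.int(l_edges[l], l_edges[l + 1] - 1L)
          annotation[li + 1L, yi + 1L, xi + 1L] <- lay_id
        }
      }
    }
  }
  structure(list(annotation = annotation, ontology = ontology,
                 voxel_size = as.numeric(voxel_size),
                 midline_axis = 3L, midline_index = shape[3] %/% 2L,
                 ap_axis = 1L),
            class = "atlas_bundle")
}

# integer slab boundaries: n_parts half-open slabs covering lo..hi (0-based)
slab_edges <- function(lo, hi, n_parts) {
  edges <- lo + round(seq(0, hi - lo + 1, length.out = n_parts + 1))
  if (any(diff(edges) < 1)) stop("infeasible partition: empty slab")
  as.integer(edges)
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> %s voxels, %d ontology nodes (%d annotated labels), midline x=%d\n",
              paste(dim(x$annotation), collapse = " x "),
              nrow(x$ontology), length(setdiff(unique(as.vector(x$annotation)), 0L)),
              x$midline_index))
  invisible(x)
}

#' Write / read an atlas bundle
#'
#' Annotation as 16-bit TIFF, ontology and geometry as JSON.
#' @param atlas an `atlas_bundle`.
#' @param annotation_path TIFF path for the label volume.
#' @param ontology_path JSON path for the tree + geometry metadata.
#' @export
write_atlas <- function(atlas, annotation_path, ontology_path) {
  write_volume(list(data = atlas$annotation * 1), annotation_path)
  meta <- list(voxel_size = atlas$voxel_size, midline_axis = atlas$midline_axis,
               midline_index = atlas$midline_index, ap_axis = atlas$ap_axis,
               ontology = atlas$ontology)
  jsonlite::write_json(meta, ontology_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(NULL)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(annotation_path, ontology_path) {
  meta <- jsonlite::read_json(ontology_path, simplifyVector = TRUE)
  vol <- read_volume(annotation_path, voxel_size = meta$voxel_size)
  ont <- meta$ontology
  ont$parent_id <- as.integer(ont$parent_id)
  ont$id <- as.integer(ont$id)
  ont$level <- as.integer(ont$level)
  if (is.null(ont$layer)) ont$layer <- NA_character_
  ann <- vol$data
  storage.mode(ann) <- "integer"
  structure(list(annotation = ann, ontology = ont,
                 voxel_size = as.numeric(meta$voxel_size),
                 midline_axis = as.integer(meta$midline_axis),
                 midline_index = as.integer(meta$midline_index),
                 ap_axis = as.integer(meta$ap_axis)),
            class = "atlas_bundle")
}
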